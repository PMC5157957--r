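# Small parameter sets and ad-hoc reaction systems used across test files.

# titration motif small enough for fast SSA (all abundances O(10))
smallTitration <- function() {
  regulationParameters(alphaM = 5, alphaA = 6, alphaS = 4, N = 2,
                       deltaM = 0.3, deltaA = 0.05, deltaS = 0.3,
                       kM = 0.1, kS = 0.1)
}

# build a bespoke mass-action system without going through the exported
# builders (used as an independent construction path in oracles)
customSystem <- function(species, reactions) {
  ColE2sim:::.newReactionSystem(species, reactions, "custom", list())
}

# two-state promoter: P + (implicit repressor at fixed level) <-> B
promoterSystem <- function(kOn, kOff, repressor) {
  customSystem(c("P", "B"), list(
    list(name = "bind", rate = kOn * repressor, change = c(P = -1, B = 1),
         order = c(P = 1)),
    list(name = "unbind", rate = kOff, change = c(P = 1, B = -1),
         order = c(B = 1))))
}

# immigration in pairs, single-molecule death: stationary Fano = 1.5
pairImmigrationSystem <- function(lambda = 5, delta = 1) {
  customSystem("X", list(
    list(name = "pair birth", rate = lambda, change = c(X = 2)),
    list(name = "death", rate = delta, change = c(X = -1),
         order = c(X = 1))))
}

# pure birth process
pureBirthSystem <- function(lambda) {
  customSystem("X", list(
    list(name = "birth", rate = lambda, change = c(X = 1))))
}
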