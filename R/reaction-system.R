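.newReactionSystem <- function(species, reactions, variant, params) {
  # reactions: list of list(name, rate, change = named, order = named,
  #                         timeDependent = FALSE)
  nS <- length(species); nR <- length(reactions)
  stoich <- matrix(0L, nS, nR, dimnames = list(species, NULL))
  orders <- matrix(0L, nS, nR, dimnames = list(species, NULL))
  rates <- numeric(nR); td <- logical(nR); nms <- character(nR)
  for (j in seq_len(nR)) {
    r <- reactions[[j]]
    stoich[names(r$change), j] <- as.integer(r$change)
    if (!is.null(r$order)) orders[names(r$order), j] <- as.integer(r$order)
    rates[j] <- r$rate
    td[j] <- isTRUE(r$timeDependent)
    nms[j] <- r$name
  }
  new("ReactionSystem", species = species, stoich = stoich, orders = orders,
      rates = rates, timeDependent = td, reactionNames = nms,
      variant = variant, params = params)
}

.reducedReactions <- function(p) {
  rx <- list(
    list(name = "production M", rate = p@alphaM, change = c(M = 1)),
    list(name = "degradation M", rate = p@deltaM, change = c(M = -1),
         order = c(M = 1)),
    list(name = "production A", rate = p@alphaA, change = c(A = 1)),
    list(name = "degradation A", rate = p@deltaA, change = c(A = -1),
         order = c(A = 1)),
    list(name = "production S (N*alphaS)", rate = p@N * p@alphaS,
         change = c(S = 1)),
    list(name = "degradation S", rate = p@deltaS, change = c(S = -1),
         order = c(S = 1))
  )
  # coupled degradation M+A: M always removed, A removed with prob pM,
  # implemented as two reactions with split propensities
  if (p@pM > 0)
    rx <- c(rx, list(list(name = "coupled degradation M+A (A removed)",
                          rate = p@kM * p@pM, change = c(M = -1, A = -1),
                          order = c(M = 1, A = 1))))
  if (p@pM < 1)
    rx <- c(rx, list(list(name = "coupled degradation M+A (A survives)",
                          rate = p@kM * (1 - p@pM), change = c(M = -1),
                          order = c(M = 1, A = 1))))
  if (p@pS > 0)
    rx <- c(rx, list(list(name = "coupled degradation S+A (A removed)",
                          rate = p@kS * p@pS, change = c(S = -1, A = -1),
                          order = c(S = 1, A = 1))))
  if (p@pS < 1)
    rx <- c(rx, list(list(name = "coupled degradation S+A (A survives)",
                          rate = p@kS * (1 - p@pS), change = c(S = -1),
                          order = c(S = 1, A = 1))))
  rx
}

.defaultDetailedRates <- function(p) {
  # complex rates recovering the reduced defaults in the fast limit:
  # kS = deltaS*vPlus/vMinus, kM = kPlus*deltaCma/kMinus (see
  # effectiveSrnaReduction); resolution rates are an order of magnitude
  # above the fastest production/degradation rate
  list(vPlus = if (p@deltaS > 0) 10 * p@kS / p@deltaS else 10,
       vMinus = 10,
       kPlus = p@kM, kMinus = 10, deltaCma = 10)
}

.detailedReactions <- function(p, dr) {
  N <- as.integer(round(p@N))
  cn <- paste0("C", 0:N)
  rx <- list(
    list(name = "production M", rate = p@alphaM, change = c(M = 1)),
    list(name = "degradation M", rate = p@deltaM, change = c(M = -1),
         order = c(M = 1)),
    list(name = "production A", rate = p@alphaA, change = c(A = 1)),
    list(name = "degradation A", rate = p@deltaA, change = c(A = -1),
         order = c(A = 1)),
    list(name = "production sRNA (C0)", rate = p@alphaS,
         change = c(C0 = 1)),
    # mRNA-CsrA complex
    list(name = "complex formation M+A -> Cma", rate = dr$kPlus,
         change = c(M = -1, A = -1, Cma = 1), order = c(M = 1, A = 1)),
    list(name = "complex dissociation Cma -> M+A", rate = dr$kMinus,
         change = c(M = 1, A = 1, Cma = -1), order = c(Cma = 1)),
    list(name = "complex degradation Cma", rate = dr$deltaCma,
         change = c(Cma = -1), order = c(Cma = 1)),
    # lysis protein from free long mRNA
    list(name = "translation L", rate = dr$betaL %||% 1,
         change = c(L = 1), order = c(M = 1)),
    list(name = "degradation L", rate = dr$deltaL %||% 0.05,
         change = c(L = -1), order = c(L = 1))
  )
  for (n in 0:N) {
    Cn <- cn[n + 1L]
    ch <- -1L; names(ch) <- Cn
    # sRNA degradation removes the molecule with all bound CsrA
    rx <- c(rx, list(list(name = sprintf("degradation sRNA (%s)", Cn),
                          rate = p@deltaS, change = ch,
                          order = stats::setNames(1L, Cn))))
    if (n < N) {
      # binding with free-site combinatorial factor (N - n)
      ch2 <- c(-1L, -1L, 1L)
      names(ch2) <- c("A", Cn, cn[n + 2L])
      rx <- c(rx, list(list(
        name = sprintf("CsrA binding %s -> %s [(N-n)=%d]", Cn, cn[n + 2L],
                       N - n),
        rate = dr$vPlus * (N - n), change = ch2,
        order = stats::setNames(c(1L, 1L), c("A", Cn)))))
    }
    if (n > 0) {
      ch3 <- c(1L, 1L, -1L)
      names(ch3) <- c("A", cn[n], Cn)
      rx <- c(rx, list(list(
        name = sprintf("CsrA unbinding %s -> %s [n=%d]", Cn, cn[n], n),
        rate = dr$vMinus * n, change = ch3,
        order = stats::setNames(1L, Cn))))
    }
  }
  rx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a reaction system for the colicin E2 network
#'
#' Three variants are available:
#' \describe{
#'   \item{reduced}{the three-component motif of the rate equations: three
#'     productions, three degradations, and the two coupled-degradation
#'     channels. CsrA survival probabilities \code{1 - p} are implemented by
#'     splitting each coupled event into two reactions with propensities
#'     \code{k p M A} and \code{k (1-p) M A}, so the propensity sum remains
#'     the single source of randomness accounting.}
#'   \item{detailed}{the multi-site scheme: sRNA molecules carrying
#'     \code{n = 0..N} bound CsrA dimers as separate species \code{C0..CN}
#'     with combinatorial binding propensities \code{vPlus (N-n) A Cn},
#'     per-dimer unbinding \code{vMinus n Cn}, the explicit mRNA-CsrA
#'     complex \code{Cma}, and lysis-protein translation from free mRNA.
#'     Requires \code{pM = pS = 1} (a bound dimer is lost when its complex
#'     degrades).}
#'   \item{full_sos}{the reduced post-transcriptional reactions coupled to
#'     the LexA-RecA SOS network; see [fullNetworkSystem()].}
#' }
#'
#' @param params a [RegulationParameters-class].
#' @param variant one of \code{"reduced"}, \code{"detailed"},
#'   \code{"full_sos"}.
#' @param sos an [SOSParameters-class]; required for \code{"full_sos"}.
#' @param detailedRates named list of complex rates (\code{vPlus},
#'   \code{vMinus}, \code{kPlus}, \code{kMinus}, \code{deltaCma}) for the
#'   detailed variant; defaults recover the reduced rate constants in the
#'   fast-complex limit.
#' @return a [ReactionSystem-class].
#' @examples
#' buildReactionSystem(regulationParameters(), "reduced")
#' @export
buildReactionSystem <- function(params,
                                variant = c("reduced", "detailed",
                                            "full_sos"),
                                sos = NULL, detailedRates = NULL) {
  stopifnot(is(params, "RegulationParameters"))
  variant <- match.arg(variant)
  if (variant == "reduced") {
    rx <- .reducedReactions(params)
    return(.newReactionSystem(c("M", "A", "S"), rx, "reduced",
                              list(regulation = params)))
  }
  if (variant == "detailed") {
    if (params@pM < 1 || params@pS < 1)
      stop("the detailed variant requires pM = pS = 1: a CsrA dimer bound ",
           "in a complex is removed when the complex degrades")
    dr <- .defaultDetailedRates(params)
    if (!is.null(detailedRates)) dr[names(detailedRates)] <- detailedRates
    N <- as.integer(round(params@N))
    species <- c("M", "A", paste0("C", 0:N), "Cma", "L")
    rx <- .detailedReactions(params, dr)
    return(.newReactionSystem(species, rx, "detailed",
                              list(regulation = params,
                                   detailedRates = dr)))
  }
  if (is.null(sos))
    stop("variant 'full_sos' requires an SOSParameters object ",
         "(missing parameters: all SOS rates)")
  fullNetworkSystem(sos, params)
}

#' Free effective-sRNA sites of a detailed-variant state
#'
#' Maps detailed-variant abundances onto the reduced model's effective sRNA
#' coordinate: the number of free CsrA binding sites,
#' \eqn{S_{free} = \sum_n (N - n) C_n}.
#'
#' @param counts matrix of detailed-variant abundances (time x species) or a
#'   [Trajectory-class].
#' @param N number of binding sites.
#' @return numeric vector of free-site counts.
#' @export
freeSrnaSites <- function(counts, N) {
  if (is(counts, "Trajectory")) counts <- counts@counts
  N <- as.integer(round(N))
  s <- numeric(nrow(counts))
  for (n in 0:N) s <- s + (N - n) * counts[, paste0("C", n)]
  s
}

setMethod("show", "ReactionSystem", function(object) {
  cat(sprintf("ReactionSystem [%s]: %d species, %d reactions\n",
              object@variant, length(object@species), length(object@rates)))
  cat("  species:", paste(object@species, collapse = ", "), "\n")
  if (any(object@timeDependent))
    cat(sprintf("  %d reaction(s) scaled by the c_p(t) schedule\n",
                sum(object@timeDependent)))
})

#' Serialize a reaction system to a human-readable text format
#'
#' One line per reaction: name, rate expression and net stoichiometric
#' change, suitable for auditing the simulated reaction list.
#'
#' @param system a [ReactionSystem-class].
#' @param path optional file path; if omitted the lines are returned.
#' @return invisibly, the character vector of lines.
#' @export
writeReactionList <- function(system, path = NULL) {
  stopifnot(is(system, "ReactionSystem"))
  lines <- character(length(system@rates))
  for (j in seq_along(system@rates)) {
    ord <- system@orders[, j]
    lhs <- names(ord)[ord > 0]
    prop <- paste(c(format(system@rates[j]),
                    if (system@timeDependent[j]) "c_p(t)",
                    lhs), collapse = " * ")
    ch <- system@stoich[, j]
    chs <- paste(sprintf("%+d %s", ch[ch != 0], names(ch)[ch != 0]),
                 collapse = ", ")
    lines[j] <- sprintf("%-45s propensity = %-28s change: %s",
                        system@reactionNames[j], prop, chs)
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
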