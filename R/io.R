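# Config keys use the field's symbol names; S4 slots use camelCase.
.regKeyMap <- c(alpha_M = "alphaM", alpha_A = "alphaA", alpha_S = "alphaS",
                N = "N", delta_M = "deltaM", delta_A = "deltaA",
                delta_S = "deltaS", k_M = "kM", k_S = "kS",
                p_M = "pM", p_S = "pS", n_sos = "nSos",
                cell_volume = "cellVolume")

.sosKeyMap <- c(alpha_Mlex = "alphaMlex", alpha_Mrec = "alphaMrec",
                alpha_Ms = "alphaMs", alpha_Ml = "alphaMl",
                beta_lex = "betaLex", beta_rec = "betaRec",
                delta_Mlex = "deltaMlex", delta_Mrec = "deltaMrec",
                delta_Ms = "deltaMs", delta_Le = "deltaLe",
                delta_R = "deltaR", beta_L = "betaL", delta_L = "deltaL",
                k_on = "kOn", k_off = "kOff", c_p = "cP")

.checkKeys <- function(given, allowed, section) {
  unknown <- setdiff(given, allowed)
  if (!length(unknown)) return(invisible())
  msgs <- vapply(unknown, function(k) {
    near <- agrep(k, allowed, max.distance = 0.3, value = TRUE)
    if (length(near))
      sprintf("'%s' (did you mean %s?)", k,
              paste(sQuote(near), collapse = " or "))
    else sprintf("'%s'", k)
  }, character(1))
  stop("unknown key(s) in section '", section, "': ",
       paste(msgs, collapse = ", "), call. = FALSE)
}

.sectionToObject <- function(sect, keyMap, ctor, section) {
  if (is.null(sect)) sect <- list()
  .checkKeys(names(sect), names(keyMap), section)
  args <- stats::setNames(lapply(sect, as.numeric),
                          keyMap[names(sect)])
  bad <- names(args)[!vapply(args, function(v)
    length(v) == 1L && is.finite(v), logical(1))]
  if (length(bad))
    stop("ill-typed value(s) in section '", section, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  do.call(ctor, args)
}

#' Load a run configuration
#'
#' Reads a YAML configuration with sections \code{posttranscription} (the
#' reduced-model rates, keys \code{alpha_M}, \code{alpha_A}, \code{alpha_S},
#' \code{N}, \code{delta_M}, \code{delta_A}, \code{delta_S}, \code{k_M},
#' \code{k_S}, \code{p_M}, \code{p_S}, \code{n_sos}, \code{cell_volume}),
#' \code{sos} (LexA-RecA rates), \code{schedule} (list of
#' \code{[time, c_p]} pairs) and \code{run} (seed, n_realizations, t_max,
#' grid_dt). Missing keys fall back to package defaults; unknown or
#' ill-typed keys are rejected in one pass with suggestions. The shipped
#' default configuration is at
#' \code{system.file("extdata", "default-config.yaml", package = "ColE2sim")}.
#'
#' @param path path to a YAML file.
#' @return list with elements \code{regulation}
#'   ([RegulationParameters-class]), \code{sos} ([SOSParameters-class]),
#'   \code{schedule} ([SignalSchedule-class]) and \code{run} (list).
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  .checkKeys(names(cfg), c("posttranscription", "sos", "schedule", "run"),
             "<top level>")
  reg <- .sectionToObject(cfg$posttranscription, .regKeyMap,
                          regulationParameters, "posttranscription")
  sos <- .sectionToObject(cfg$sos, .sosKeyMap, sosParameters, "sos")
  sched <- if (is.null(cfg$schedule)) signalSchedule() else {
    m <- do.call(rbind, lapply(cfg$schedule, as.numeric))
    if (ncol(m) != 2L)
      stop("schedule entries must be [time, c_p] pairs", call. = FALSE)
    signalSchedule(m[, 1L], m[, 2L])
  }
  run <- cfg$run %||% list()
  .checkKeys(names(run), c("seed", "n_realizations", "t_max", "grid_dt"),
             "run")
  run <- utils::modifyList(
    list(seed = 1L, n_realizations = 500L, t_max = 700, grid_dt = 1), run)
  list(regulation = reg, sos = sos, schedule = sched, run = run)
}

#' Write a configuration file
#'
#' Serializes parameter objects back to the YAML layout read by
#' [loadConfig()], at full precision.
#'
#' @param path output path.
#' @param regulation a [RegulationParameters-class].
#' @param sos an [SOSParameters-class].
#' @param schedule a [SignalSchedule-class].
#' @param run list of run options.
#' @return invisibly, \code{path}.
#' @export
writeConfig <- function(path, regulation = regulationParameters(),
                        sos = sosParameters(),
                        schedule = signalSchedule(),
                        run = list(seed = 1L, n_realizations = 500L,
                                   t_max = 700, grid_dt = 1)) {
  toSection <- function(obj, keyMap)
    stats::setNames(lapply(keyMap, function(s) slot(obj, s)),
                    names(keyMap))
  cfg <- list(
    posttranscription = toSection(regulation, .regKeyMap),
    sos = toSection(sos, .sosKeyMap),
    schedule = mapply(function(t, v) c(t, v), schedule@times,
                      schedule@values, SIMPLIFY = FALSE),
    run = run)
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}

#' Deterministic small fixtures for testing and examples
#'
#' @param kind one of:
#'   \describe{
#'     \item{birth_death}{single-species birth-death process (rate 10,
#'       decay 1): stationary mean 10, Fano factor 1.}
#'     \item{two_component_titration}{the sRNA-free submodel (effective
#'       sRNA production 0): mRNA vs CsrA titration with just two
#'       components.}
#'     \item{reduced_default}{the default reduced-model parameters.}
#'     \item{near_threshold}{reduced parameters with combined target
#'       production within 1 percent of the threshold locus (slightly
#'       above).}
#'   }
#' @param seed integer seed stored in the fixture (generation itself is
#'   deterministic).
#' @return list with \code{params} ([RegulationParameters-class]),
#'   \code{system} ([ReactionSystem-class]), \code{kind}, \code{seed} and
#'   kind-specific analytic reference values.
#' @export
fixtureGenerator <- function(kind = c("birth_death",
                                      "two_component_titration",
                                      "reduced_default",
                                      "near_threshold"),
                             seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "birth_death") {
    p <- regulationParameters(alphaM = 10, alphaA = 0, alphaS = 0, N = 1,
                              deltaM = 1, deltaA = 1, deltaS = 1,
                              kM = 0, kS = 0)
    return(list(params = p,
                system = buildReactionSystem(p, "reduced"),
                kind = kind, seed = seed,
                analytic = list(meanM = 10, fanoM = 1)))
  }
  if (kind == "two_component_titration") {
    p <- regulationParameters(alphaM = 30, alphaA = 25, alphaS = 0, N = 1,
                              deltaM = 0.2, deltaA = 0.01, deltaS = 0.25,
                              kM = 0.1, kS = 0.1)
    return(list(params = p,
                system = buildReactionSystem(p, "reduced"),
                kind = kind, seed = seed,
                analytic = list(thresholdAlphaM = 25)))
  }
  if (kind == "reduced_default") {
    p <- regulationParameters()
    return(list(params = p,
                system = buildReactionSystem(p, "reduced"),
                kind = kind, seed = seed, analytic = list()))
  }
  # near_threshold: put combined production 0.5 percent above the locus
  p <- regulationParameters()
  locus <- thresholdCondition(p)$locusAlphaA
  target <- 1.005 * locus
  p <- setParameters(p, alphaM = max(target - p@pS * srnaProduction(p), 0) /
                       p@pM)
  list(params = p, system = buildReactionSystem(p, "reduced"),
       kind = kind, seed = seed,
       analytic = list(locusAlphaA = locus, relativeMargin = 0.005))
}

#' Run manifest for reproducibility
#'
#' Collects everything needed to reproduce a run bit-for-bit with the same
#' build: full parameter dump, schedule, seeds, package version, the
#' interpretation of the printed sRNA production value (effective
#' N*alpha_S), command line and output inventory.
#'
#' @param regulation,sos,schedule parameter objects of the run.
#' @param seed base seed.
#' @param outputs character vector of output file paths.
#' @param extra named list of additional entries.
#' @param path optional path; when given the manifest is written as JSON.
#' @return the manifest list, invisibly if written.
#' @export
runManifest <- function(regulation = regulationParameters(),
                        sos = sosParameters(),
                        schedule = signalSchedule(), seed = 1L,
                        outputs = character(), extra = list(),
                        path = NULL) {
  dump <- function(obj)
    stats::setNames(lapply(slotNames(class(obj)),
                           function(s) slot(obj, s)),
                    slotNames(class(obj)))
  man <- c(list(
    package = "ColE2sim",
    version = as.character(utils::packageVersion("ColE2sim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    commandLine = paste(commandArgs(), collapse = " "),
    seed = seed,
    regulation = dump(regulation),
    sos = dump(sos),
    schedule = list(times = schedule@times, values = schedule@values),
    srnaProductionConvention = paste(
      "printed sRNA production values denote the effective rate",
      "N*alpha_S of the one-site reduced model"),
    outputs = as.list(outputs)), extra)
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(man))
  }
  man
}

#' Write a trajectory as tidy CSV
#'
#' Long format: \code{time, species, value, realization}; numbers at full
#' precision with '.' decimal separator.
#'
#' @param x a [Trajectory-class] or [TrajectoryEnsemble-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeTrajectoryCSV <- function(x, path) {
  if (is(x, "Trajectory")) {
    df <- data.frame(
      time = rep(x@time, ncol(x@counts)),
      species = rep(colnames(x@counts), each = length(x@time)),
      value = as.numeric(x@counts),
      realization = 1L)
  } else if (is(x, "TrajectoryEnsemble")) {
    d <- dim(x@counts)
    df <- data.frame(
      time = rep(x@time, d[2L] * d[3L]),
      species = rep(rep(dimnames(x@counts)[[2L]], each = d[1L]), d[3L]),
      value = as.numeric(x@counts),
      realization = rep(seq_len(d[3L]), each = d[1L] * d[2L]))
  } else stop("unsupported object")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write phase-surface maps as CSV grids
#'
#' @param surface result of [phaseSurface()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writePhaseSurfaceCSV <- function(surface, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (sp in c("M", "A", "S")) {
    f <- file.path(dir, sprintf("steady_state_%s.csv", sp))
    utils::write.csv(surface[[sp]], f, quote = FALSE)
    paths <- c(paths, f)
  }
  f <- file.path(dir, "transition_line.csv")
  utils::write.csv(surface$transition, f, row.names = FALSE, quote = FALSE)
  invisible(c(paths, f))
}
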