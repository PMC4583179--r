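## Plain-text (YAML) configuration profiles. The built-in defaults ship as
## inst/extdata/default-profile.yaml; readFuzzedgeConfig() reconstructs the
## S4 configuration objects from such a file.

.mfFromList <- function(x) {
  type <- tolower(x$type %||% "trapezoid")
  if (type %in% c("trapezoid", "trapezoidal", "tmf")) {
    p <- as.numeric(x$params)
    stopifnot(length(p) == 4L)
    trapezoidalMF(p[1], p[2], p[3], p[4])
  } else if (type %in% c("gaussian", "gmf")) {
    gaussianMF(as.numeric(x$m), as.numeric(x$d))
  } else stop("unknown membership-function type: ", type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.setsFromList <- function(x, universe = c(0, 255)) {
  sets <- lapply(names(x), function(lab)
    fuzzySet(lab, .mfFromList(x[[lab]]), universe))
  names(sets) <- names(x)
  sets
}

.rulesFromList <- function(x) {
  lapply(x, function(r)
    fuzzyRule(higher = as.integer(r$higher %||% integer()),
              lower = as.integer(r$lower %||% integer()),
              consequent = r$consequent %||% "Edge"))
}

.detectorFromList <- function(d) {
  uni <- d$universe %||% list()
  universe <- outputUniverse(as.numeric(uni$lo %||% 0),
                             as.numeric(uni$hi %||% 255),
                             as.integer(uni$n %||% 512))
  edgeDetectorConfig(
    inputSets = if (is.null(d$input)) edgeInputSets() else .setsFromList(d$input),
    outputSets = if (is.null(d$output)) edgeOutputSets() else .setsFromList(d$output),
    rules = if (is.null(d$rules)) edgeRuleBase() else .rulesFromList(d$rules),
    universe = universe,
    threshold = as.numeric(d$threshold %||% 127.5),
    neighborOrder = as.character(d$neighbors %||% .defaultNeighborOrder))
}

.contrastFromList <- function(d) {
  if (is.null(d$input) && is.null(d$output)) return(defaultContrastConfig())
  rules <- if (is.null(d$rules)) c(Darker = "Darkest", Grey = "Grey",
                                   Brighter = "Brightest")
           else unlist(d$rules)
  contrastConfig(inputSets = .setsFromList(d$input),
                 outputSets = .setsFromList(d$output),
                 rules = rules)
}

#' Load a configuration profile from a YAML file
#'
#' The file may contain `detector`, `contrast` and `noise` sections; any
#' missing section falls back to the built-in defaults. See
#' `system.file("extdata", "default-profile.yaml", package = "fuzzedge")`
#' for the reference profile carrying the default fuzzy-set parameters and
#' the 12-rule knowledge base.
#'
#' @param path path to a YAML profile.
#' @return list with elements `detector` ([DetectorConfig-class]),
#'   `contrast` ([ContrastConfig-class]) and `noise` (list of `psnr`,
#'   `seed`).
#' @export
readFuzzedgeConfig <- function(path) {
  if (!file.exists(path)) stop("cannot read config file: ", path)
  y <- yaml::read_yaml(path)
  list(detector = .detectorFromList(y$detector %||% list()),
       contrast = .contrastFromList(y$contrast %||% list()),
       noise = list(psnr = as.numeric(y$noise$psnr %||% 25),
                    seed = if (is.null(y$noise$seed)) NULL
                           else as.integer(y$noise$seed)))
}
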