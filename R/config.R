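#' Create a fusion configuration
#'
#' Bundles the alignment parameters: the window length W and the similarity
#' threshold vector (thetaN, thetaT, thetaLN), plus the structure metric and
#' label-preconditioning options. Defaults follow the values found to work
#' well on real cell-ontology fusions: W = 4, thetaN = 0.85, thetaLN = 0.7.
#' thetaT has no canonical default and is set to 0.7, matching thetaLN.
#'
#' @param W positive integer window length.
#' @param thetaN,thetaT,thetaLN thresholds in \[0,1\]; see
#'   [FusionConfig-class].
#' @param metric structure metric: "cosine", "euclidean", "pearson",
#'   "constraint" or "blondel".
#' @param useSynonyms maximise name similarity over synonym lists.
#' @param stopWords,stripChars label preconditioning sets used by
#'   [normalizeLabel()].
#' @param synonymSep separator of inline synonym lists in tabular input.
#' @param threads workers for the structure-matrix loop.
#' @return A validated [FusionConfig-class].
#' @examples
#' fusionConfig(W = 2, metric = "blondel")
#' @export
fusionConfig <- function(W = 4L, thetaN = 0.85, thetaT = 0.7, thetaLN = 0.7,
                         metric = "cosine", useSynonyms = TRUE,
                         stopWords = character(), stripChars = character(),
                         synonymSep = "|", threads = 1L) {
  cfg <- new("FusionConfig",
             W = as.integer(W), thetaN = as.numeric(thetaN),
             thetaT = as.numeric(thetaT), thetaLN = as.numeric(thetaLN),
             metric = as.character(metric)[1L],
             useSynonyms = isTRUE(useSynonyms),
             stopWords = as.character(stopWords),
             stripChars = as.character(stripChars),
             synonymSep = as.character(synonymSep)[1L],
             threads = as.integer(threads))
  validObject(cfg)
  cfg
}

setMethod("show", "FusionConfig", function(object) {
  cat(sprintf(
    "FusionConfig: W=%d, thetaN=%.2f, thetaT=%.2f, thetaLN=%.2f, metric=%s\n",
    object@W, object@thetaN, object@thetaT, object@thetaLN, object@metric))
  cat(sprintf("  useSynonyms=%s, threads=%d\n",
              object@useSynonyms, object@threads))
  if (length(object@stopWords))
    cat("  stopWords:", paste(object@stopWords, collapse = ", "), "\n")
  if (length(object@stripChars))
    cat("  stripChars:", paste(object@stripChars, collapse = " "), "\n")
})

#' Read a fusion configuration file
#'
#' The file holds flat UTF-8 `key = value` lines; `#` starts a comment and
#' blank lines are ignored; list values (stop_words, strip_chars) are
#' comma-separated. Unknown keys are warned about and skipped; missing keys
#' take the defaults of [fusionConfig()]. Accepted keys: `W`, `theta_N`,
#' `theta_T`, `theta_LN`, `metric`, `use_synonyms`, `stop_words`,
#' `strip_chars`, `synonym_sep`, `threads`.
#'
#' @param path path to the configuration file.
#' @return A validated [FusionConfig-class].
#' @export
readFusionConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      warning("ignoring malformed config line: ", ln)
      next
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parsed <- switch(key,
      W        = list(W = .cfgInt(key, val)),
      theta_N  = list(thetaN = .cfgNum(key, val)),
      theta_T  = list(thetaT = .cfgNum(key, val)),
      theta_LN = list(thetaLN = .cfgNum(key, val)),
      metric   = list(metric = val),
      use_synonyms = list(useSynonyms = .cfgBool(key, val)),
      stop_words   = list(stopWords = .cfgList(val)),
      strip_chars  = list(stripChars = .cfgList(val)),
      synonym_sep  = list(synonymSep = val),
      threads      = list(threads = .cfgInt(key, val)),
      {
        warning("unknown config key: ", key)
        NULL
      })
    if (!is.null(parsed)) args[names(parsed)] <- parsed
  }
  tryCatch(do.call(fusionConfig, args), error = function(e)
    stop("invalid configuration in ", path, ": ", conditionMessage(e),
         call. = FALSE))
}

.cfgNum <- function(key, val) {
  x <- suppressWarnings(as.numeric(val))
  if (is.na(x)) stop("config key ", key, " is not a number: ", val,
                     call. = FALSE)
  x
}

.cfgInt <- function(key, val) as.integer(.cfgNum(key, val))

.cfgBool <- function(key, val) {
  v <- tolower(val)
  if (v %in% c("true", "yes", "1")) return(TRUE)
  if (v %in% c("false", "no", "0")) return(FALSE)
  stop("config key ", key, " is not a boolean: ", val, call. = FALSE)
}

.cfgList <- function(val) {
  out <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
  out[nzchar(out)]
}
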