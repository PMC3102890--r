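`%||%` <- function(a, b) if (is.null(a)) b else a

phare_error <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "phare_error")))
}

#' Encode a display name as an identifier-safe local name
#'
#' Spaces in compound nouns are replaced by `=`, mirroring the convention
#' used for RDF local names such as `parkinson=disease`.
#'
#' @param x character vector of display names.
#' @return character vector of local names.
#' @export
encode_local_name <- function(x) {
  gsub("[[:space:]]+", "=", trimws(x))
}

#' @rdname encode_local_name
#' @export
decode_local_name <- function(x) {
  gsub("=", " ", x, fixed = TRUE)
}

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Candidate label forms for case-insensitive matching with a light
# pluralization fallback: the exact (lowercased) word, then the word with a
# trailing "s" stripped, then with a trailing "es" stripped.
label_variants <- function(word) {
  w <- tolower(word)
  out <- w
  if (grepl("s$", w)) out <- c(out, sub("s$", "", w))
  if (grepl("es$", w)) out <- c(out, sub("es$", "", w))
  unique(out[nzchar(out)])
}

is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
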