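# Raw-relationship files: JSON-lines (one object per line with fields
# raw_type, subject_tokens, object_tokens, pmid, sentence) and a TSV
# dialect where token sequences are space-joined.

#' Read raw relationships
#'
#' @param path input file.
#' @param format `"jsonl"` (default) or `"tsv"`.
#' @return list of `phare_raw`.
#' @export
read_raw_relationships <- function(path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    return(lapply(lines, function(l) {
      x <- jsonlite::fromJSON(l)
      raw_relationship(x$raw_type, x$subject_tokens, x$object_tokens,
                       x$pmid, x$sentence)
    }))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  lapply(seq_len(nrow(df)), function(i) {
    raw_relationship(df$raw_type[i],
                     strsplit(df$subject[i], " ", fixed = TRUE)[[1]],
                     strsplit(df$object[i], " ", fixed = TRUE)[[1]],
                     df$pmid[i], df$sentence[i])
  })
}

#' @rdname read_raw_relationships
#' @param raws list of `phare_raw`.
#' @export
write_raw_relationships <- function(raws, path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- vapply(raws, function(r) {
      jsonlite::toJSON(list(raw_type = jsonlite::unbox(r$raw_type),
                            subject_tokens = r$subject_tokens,
                            object_tokens = r$object_tokens,
                            pmid = jsonlite::unbox(r$pmid),
                            sentence = jsonlite::unbox(r$sentence)))
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    df <- data.frame(
      raw_type = vapply(raws, `[[`, character(1), "raw_type"),
      subject = vapply(raws, function(r) paste(r$subject_tokens, collapse = " "),
                       character(1)),
      object = vapply(raws, function(r) paste(r$object_tokens, collapse = " "),
                      character(1)),
      pmid = vapply(raws, `[[`, character(1), "pmid"),
      sentence = vapply(raws, `[[`, character(1), "sentence"),
      stringsAsFactors = FALSE
    )
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write a synonym resource
#'
#' Plain text, one whitespace-separated synset per line. A word may appear
#' in several synsets, as in real synonym inventories.
#'
#' @param path file path.
#' @return `read_synsets` returns a list of character vectors.
#' @export
read_synsets <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, function(l) strsplit(l, "[[:space:]]+")[[1]])
}

#' @rdname read_synsets
#' @param synsets list of character vectors.
#' @export
write_synsets <- function(synsets, path) {
  writeLines(vapply(synsets, paste, character(1), collapse = " "), path,
             useBytes = TRUE)
  invisible(path)
}
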