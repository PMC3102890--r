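# Minimal line-oriented Turtle / N-Triples layer.
#
# The package serializes ontologies and knowledge bases into a restricted
# RDF profile: one statement per line, prefixed names, quoted literals, and
# a single one-line blank-node pattern (the owl:Restriction used for
# modifier restrictions and composition axioms). Local names may contain
# '=' (the space-encoding convention), which rules out off-the-shelf strict
# parsers; this layer reads back exactly the profile it writes.

phare_prefixes <- c(
  phare = "http://phare-kb.org/phare#",
  rdf   = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs  = "http://www.w3.org/2000/01/rdf-schema#",
  owl   = "http://www.w3.org/2002/07/owl#"
)

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x
}

ttl_unescape <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    chars <- strsplit(x[[i]], "", fixed = TRUE)[[1]]
    buf <- character(0)
    j <- 1
    while (j <= length(chars)) {
      ch <- chars[[j]]
      if (ch == "\\" && j < length(chars)) {
        nxt <- chars[[j + 1]]
        buf <- c(buf, switch(nxt, n = "\n", r = "\r", t = "\t", nxt))
        j <- j + 2
      } else {
        buf <- c(buf, ch)
        j <- j + 1
      }
    }
    out[[i]] <- paste(buf, collapse = "")
  }
  out
}

ttl_literal <- function(x) paste0("\"", ttl_escape(x), "\"")

is_literal_term <- function(x) startsWith(x, "\"")

literal_value <- function(x) ttl_unescape(sub("^\"(.*)\"$", "\\1", x))

restriction_term <- function(inner) {
  sprintf(paste0("[ rdf:type owl:Restriction ; owl:onProperty phare:modified",
                 " ; owl:someValuesFrom %s ]"), inner)
}

is_restriction_term <- function(x) startsWith(x, "[")

restriction_inner <- function(x) {
  m <- regmatches(x, regexpr("owl:someValuesFrom +[^] ]+", x))
  if (!length(m)) {
    phare_error(sprintf("malformed restriction term: %s", x),
                class = "phare_format_error")
  }
  sub("^owl:someValuesFrom +", "", m)
}

statement_df <- function(s = character(), p = character(), o = character()) {
  data.frame(s = s, p = p, o = o, stringsAsFactors = FALSE)
}

# Tokenize one statement line into its terms (the trailing '.' dropped).
split_statement <- function(line) {
  rest <- trimws(line)
  terms <- character()
  while (nzchar(rest)) {
    if (startsWith(rest, "\"")) {
      m <- regexpr('^"(\\\\.|[^"\\\\])*"', rest)
    } else if (startsWith(rest, "[")) {
      m <- regexpr("^\\[[^]]*\\]", rest)
    } else {
      m <- regexpr("^[^ \t]+", rest)
    }
    if (m == -1L) {
      phare_error(sprintf("cannot tokenize statement: %s", line),
                  class = "phare_format_error")
    }
    len <- attr(m, "match.length")
    terms <- c(terms, substr(rest, 1, len))
    rest <- trimws(substring(rest, len + 1))
  }
  if (length(terms) && terms[[length(terms)]] == ".") {
    terms <- terms[-length(terms)]
  }
  if (length(terms) != 3) {
    phare_error(sprintf("expected 3 terms in statement: %s", line),
                class = "phare_format_error")
  }
  terms
}

expand_term <- function(x) {
  if (is_literal_term(x) || startsWith(x, "_:")) return(x)
  pfx <- sub(":.*$", "", x)
  if (!(pfx %in% names(phare_prefixes))) {
    phare_error(sprintf("unknown prefix in term %s", x),
                class = "phare_format_error")
  }
  paste0("<", phare_prefixes[[pfx]], sub("^[^:]+:", "", x), ">")
}

contract_term <- function(x) {
  if (is_literal_term(x) || startsWith(x, "_:")) return(x)
  iri <- sub("^<(.*)>$", "\\1", x)
  for (pfx in names(phare_prefixes)) {
    base <- phare_prefixes[[pfx]]
    if (startsWith(iri, base)) {
      return(paste0(pfx, ":", substring(iri, nchar(base) + 1)))
    }
  }
  phare_error(sprintf("IRI outside known namespaces: %s", x),
              class = "phare_format_error")
}

# Write statements (data frame with s/p/o, terms already in prefixed form,
# restriction terms as one-line brackets) to Turtle or N-Triples.
write_statements <- function(df, path, format = c("turtle", "ntriples")) {
  format <- match.arg(format)
  if (format == "turtle") {
    header <- sprintf("@prefix %s: <%s> .", names(phare_prefixes), phare_prefixes)
    body <- sprintf("%s %s %s .", df$s, df$p, df$o)
    writeLines(c(header, "", body), path, useBytes = TRUE)
    return(invisible(path))
  }
  # N-Triples: expand bracket terms into numbered blank nodes.
  lines <- character()
  bn <- 0L
  for (i in seq_len(nrow(df))) {
    s <- df$s[[i]]; p <- df$p[[i]]; o <- df$o[[i]]
    emit_bn <- function(term) {
      bn <<- bn + 1L
      id <- sprintf("_:b%d", bn)
      inner <- restriction_inner(term)
      lines <<- c(
        lines,
        sprintf("%s %s %s .", id, expand_term("rdf:type"), expand_term("owl:Restriction")),
        sprintf("%s %s %s .", id, expand_term("owl:onProperty"), expand_term("phare:modified")),
        sprintf("%s %s %s .", id, expand_term("owl:someValuesFrom"), expand_term(inner))
      )
      id
    }
    if (is_restriction_term(s)) s <- emit_bn(s) else s <- expand_term(s)
    p <- expand_term(p)
    if (is_restriction_term(o)) o <- emit_bn(o) else o <- expand_term(o)
    lines <- c(lines, sprintf("%s %s %s .", s, p, o))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# Read statements back; blank-node restriction groups are re-collapsed into
# one-line bracket terms so callers see the same representation either way.
read_statements <- function(path) {
  if (!file.exists(path)) {
    phare_error(sprintf("file not found: %s", path), class = "phare_io_error")
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "@prefix")]
  if (!length(lines)) return(statement_df())
  terms <- lapply(lines, split_statement)
  s <- vapply(terms, `[[`, character(1), 1)
  p <- vapply(terms, `[[`, character(1), 2)
  o <- vapply(terms, `[[`, character(1), 3)
  ntriples <- any(startsWith(s, "<") | startsWith(p, "<"))
  if (ntriples) {
    s <- vapply(s, contract_term, character(1), USE.NAMES = FALSE)
    p <- vapply(p, contract_term, character(1), USE.NAMES = FALSE)
    o <- vapply(o, contract_term, character(1), USE.NAMES = FALSE)
  }
  df <- statement_df(s, p, o)
  member_preds <- c("rdf:type", "owl:onProperty", "owl:someValuesFrom")
  blank <- startsWith(df$s, "_:") & df$p %in% member_preds &
    df$o %in% c("owl:Restriction", "phare:modified") |
    (startsWith(df$s, "_:") & df$p == "owl:someValuesFrom")
  if (any(blank)) {
    groups <- split(df[blank, ], df$s[blank])
    repl <- vapply(groups, function(g) {
      inner <- g$o[g$p == "owl:someValuesFrom"]
      if (length(inner) != 1) {
        phare_error("malformed blank-node restriction group",
                    class = "phare_format_error")
      }
      restriction_term(inner)
    }, character(1))
    df <- df[!blank, , drop = FALSE]
    hit <- df$o %in% names(repl)
    df$o[hit] <- repl[df$o[hit]]
    hit <- df$s %in% names(repl)
    df$s[hit] <- repl[df$s[hit]]
  }
  rownames(df) <- NULL
  df
}
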