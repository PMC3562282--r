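#' Read and write corpora in the JSON-lines corpus dialect
#'
#' One record per line, one construction per record:
#' `{"tokens": [...], "meaning": [{"sw":1,"clause":"main","role":"A"}, ...],
#'   "meta": {...}}`.
#' The first line is a header record
#' `{"format":"esnparse-corpus","version":1,"scheme_id":"ext462"}`.
#' `write_corpus` followed by `read_corpus` is the identity on a corpus up
#' to the provenance attribute (which becomes `"loaded"`).
#'
#' @param x An `esn_corpus`.
#' @param path File path.
#' @param scheme Optional [coding_scheme()] used to validate token symbols
#'   on read; defaults to the scheme named in the file header.
#' @return `read_corpus` returns an `esn_corpus`; `write_corpus` returns
#'   `path` invisibly.
#' @export
write_corpus <- function(x, path) {
  stopifnot(inherits(x, "esn_corpus"))
  header <- jsonlite::toJSON(list(format = "esnparse-corpus", version = 1L,
                                  scheme_id = attr(x, "scheme_id")),
                             auto_unbox = TRUE)
  lines <- vapply(x, function(cc) {
    meta <- cc$meta[!vapply(cc$meta, is.null, logical(1))]
    jsonlite::toJSON(list(tokens = cc$tokens,
                          meaning = cc$meaning,
                          meta = meta),
                     auto_unbox = TRUE, dataframe = "rows", na = "null")
  }, character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path, scheme = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty corpus file: ", path)
  header <- tryCatch(jsonlite::fromJSON(lines[1]),
                     error = function(e) stop("line 1: malformed header (",
                                              conditionMessage(e), ")"))
  if (!identical(header$format, "esnparse-corpus")) {
    stop("line 1: not an esnparse corpus file")
  }
  scheme_id <- header$scheme_id
  if (is.null(scheme)) {
    scheme <- coding_scheme(scheme_id,
                            modifiers = identical(scheme_id, "ext462"))
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  cons <- vector("list", length(body))
  for (i in seq_along(body)) {
    rec <- tryCatch(jsonlite::fromJSON(body[i], simplifyVector = TRUE),
                    error = function(e) stop("line ", i + 1L,
                                             ": parse error (",
                                             conditionMessage(e), ")"))
    toks <- as.character(rec$tokens)
    unknown <- setdiff(unique(toks), scheme$vocab)
    if (length(unknown)) {
      stop("line ", i + 1L, ": unknown token symbol(s): ",
           paste(unknown, collapse = ", "))
    }
    meaning <- as.data.frame(rec$meaning, stringsAsFactors = FALSE)
    meaning$sw <- as.integer(meaning$sw)
    meta <- as.list(rec$meta)
    for (f in c("main_arity", "attach", "n_sw", "group")) {
      if (!is.null(meta[[f]]) && !is.na(meta[[f]][1])) {
        meta[[f]] <- as.integer(meta[[f]])
      }
    }
    cons[[i]] <- tryCatch(construction(toks, meaning, meta),
                          error = function(e) stop("line ", i + 1L, ": ",
                                                   conditionMessage(e)))
  }
  corpus(cons, scheme_id = scheme_id, provenance = "loaded")
}
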