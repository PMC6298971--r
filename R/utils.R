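# Shared helpers: deterministic formatting and sub-seeding.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

EVIDENCE_SOURCES <- c("pfam", "dbcan", "cazy_blast", "tigrfam", "sulfatlas", "merops")

CAZY_FAMILY_RE <- "^(GH|PL|CE|CBM|AA)[0-9]+"

#' Derive a reproducible stream seed from a master seed
#'
#' Each synthetic output draws from its own pseudo-random stream so that
#' adding one output never perturbs the others. Stream seeds are derived
#' deterministically from the master seed and a stream name, and stay below
#' 2^31.
#'
#' @param master integer master seed.
#' @param stream character stream name.
#' @return An integer seed.
#' @export
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream))
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% 1000003L
  as.integer((abs(master) %% 1000003L) * 1009L + h) %% 2147483629L
}

# 6-significant-digit float serialization so repeated runs are byte-identical
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    formatC(v, digits = 6L, format = "g")
  }, character(1L))
  out
}

# Format numeric columns of a data frame and write a deterministic TSV.
write_tsv_stable <- function(df, path, sort_by = NULL) {
  df <- as.data.frame(df)
  if (!is.null(sort_by) && sort_by %in% names(df)) {
    df <- df[order(df[[sort_by]]), , drop = FALSE]
  }
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- fmt_num(df[[j]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

validate_protein <- function(seq, what = "sequence") {
  if (length(seq) != 1L || is.na(seq) || nchar(seq) == 0L) {
    stop(what, " must be a non-empty amino-acid string", call. = FALSE)
  }
  bad <- setdiff(strsplit(seq, "")[[1]], c(AA20, "X"))
  if (length(bad) > 0L) {
    stop(what, " contains non-amino-acid characters: ",
         paste(unique(bad), collapse = ","), call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
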