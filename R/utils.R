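# shared constants and small internal helpers

# 20 proteinogenic amino acids, single-letter codes
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# pre-curation junctions may also carry stop codons and frame markers
AA_ALPHABET_RAW <- c(AA_ALPHABET, "*", "_")

is_aa_string <- function(x, alphabet = AA_ALPHABET) {
  chars <- strsplit(x, "", fixed = TRUE)
  vapply(chars, function(ch) all(ch %in% alphabet), logical(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

# deterministic TSV writer: fixed quoting/eol so identical inputs give
# byte-identical files
write_tsv_plain <- function(df, path) {
  utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_plain <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = NA, na.strings = "NA")
}
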