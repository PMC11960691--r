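#' Write sequences as FASTA (60-column wrap)
#' @param seqs named character vector
#' @param file path
#' @export
write_fasta <- function(seqs, file) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, file, width = 60)
}

#' Read a FASTA file as a named character vector
#' @param file path
#' @export
read_fasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  setNames(as.character(x), names(x))
}

# header comment lines carrying provenance for every text output
output_header <- function(config = NULL) {
  h <- c(paste0("msyscan ", pkg_version()))
  if (!is.null(config)) {
    cfg_hash <- substr(digest_config(config), 1, 12)
    h <- c(h, paste0("config_hash: ", cfg_hash),
           paste0("seed: ", config$seed))
  }
  h
}

digest_config <- function(config) {
  s <- paste(names(config), vapply(config, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  # small stable polynomial hash; avoids a digest dependency
  bytes <- utf8ToInt(s)
  h1 <- 17; h2 <- 7919
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% 2147483647
    h2 <- (h2 * 131 + b) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}

#' Write a data frame as TSV with `#` header comments
#' @param df data frame
#' @param file path
#' @param header character vector of comment lines (no leading `#`)
#' @export
write_tsv <- function(df, file, header = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.4f", x))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a TSV written by [write_tsv()]
#' @param file path
#' @export
read_tsv <- function(file) {
  read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write intervals as BED (0-based half-open)
#' @param df data frame with `chrom`, `start`, `end` and optional further
#'   columns
#' @param file path
#' @param header comment lines
#' @export
write_bed <- function(df, file, header = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Read a BED file (0-based half-open)
#' @param file path
#' @param col_names names for the columns present
#' @export
read_bed <- function(file, col_names = c("chrom", "start", "end", "name")) {
  df <- read.delim(file, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  names(df) <- col_names[seq_len(ncol(df))]
  df
}
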