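#' Read a reference genome from FASTA
#'
#' @param path path to a (possibly gzipped) FASTA file.
#' @return named character vector, one uppercase sequence per chromosome;
#'   names are truncated at the first whitespace as in common FASTA headers.
#' @export
read_reference <- function(path) {
    ss <- Biostrings::readDNAStringSet(path)
    seqs <- toupper(as.character(ss))
    names(seqs) <- sub("\\s.*$", "", names(ss))
    seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(seqs)) {
        writeLines(paste0(">", names(seqs)[i]), con)
        s <- seqs[[i]]
        n <- nchar(s)
        starts <- seq(1L, max(n, 1L), by = width)
        writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
    }
    invisible(path)
}

#' Read sequencing reads
#'
#' Accepts a FASTQ/FASTA path (optionally gzipped) or a character vector of
#' read sequences, and returns an uppercase character vector.
#'
#' @param x path or character vector of sequences.
#' @export
read_reads <- function(x) {
    if (length(x) != 1L || !file.exists(x)) {
        return(toupper(as.character(x)))
    }
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", x, ignore.case = TRUE)) "fastq" else "fasta"
    toupper(as.character(Biostrings::readDNAStringSet(x, format = fmt)))
}

#' Write reads to FASTQ
#'
#' Placeholder base qualities are used (the genotyping model consumes k-mer
#' counts only).
#'
#' @param reads character vector of read sequences.
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @param ids optional read names.
#' @export
write_fastq <- function(reads, path, ids = NULL) {
    if (is.null(ids)) ids <- sprintf("read%d", seq_along(reads))
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    qual <- vapply(nchar(reads), function(n) strrep("I", n), "")
    writeLines(paste0("@", ids, "\n", reads, "\n+\n", qual), con)
    invisible(path)
}
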