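# k-mer index: canonical k-mer counts along haplotype paths (graph side),
# counts of graph k-mers in the sample reads (read side), bubble-unique
# k-mer selection and mean k-mer coverage estimation.

new_kmer_table <- function(ptr, k) structure(list(ptr = ptr, k = as.integer(k)),
                                             class = "kmer_table")

#' @export
print.kmer_table <- function(x, ...) {
    cat(sprintf("k-mer count table: k=%d, %s distinct canonical k-mers\n",
                x$k, format(.cpp_kmer_table_size(x$ptr), big.mark = ",")))
    invisible(x)
}

#' Count all k-mers along the haplotype paths of a pangenome
#'
#' Every haplotype path sequence (reference with that haplotype's bubble
#' alleles substituted, including all flanking sequence) is scanned and
#' canonical k-mer occurrences are accumulated across the N paths.
#'
#' @param pg a `"pangenome"`.
#' @return a `"kmer_table"` (graph side).
#' @export
count_graph_kmers <- function(pg) {
    seqs <- unlist(haplotype_path_seqs(pg), use.names = FALSE)
    new_kmer_table(.cpp_kmer_table_build(seqs, pg$k), pg$k)
}

#' Count graph k-mers in sequencing reads
#'
#' Only k-mers that are present in the graph table are counted; k-mer windows
#' containing non-ACGT bases are skipped. Counting is canonical, hence
#' strand-symmetric.
#'
#' @param reads FASTQ/FASTA path (optionally gzipped) or character vector of
#'   read sequences.
#' @param graph_tab the graph-side `"kmer_table"` defining the k-mer universe.
#' @return a `"kmer_table"` (read side).
#' @export
count_read_kmers <- function(reads, graph_tab) {
    stopifnot(inherits(graph_tab, "kmer_table"))
    reads <- read_reads(reads)
    new_kmer_table(.cpp_kmer_count_in(graph_tab$ptr, reads, graph_tab$k),
                   graph_tab$k)
}

#' Look up counts of k-mers in a count table
#'
#' @param tab a `"kmer_table"`.
#' @param kmers character vector of k-mers (any strand; canonicalized before
#'   lookup). Returns 0 for absent k-mers, NA for k-mers of the wrong length
#'   or containing non-ACGT bases.
#' @export
kmer_counts <- function(tab, kmers) {
    stopifnot(inherits(tab, "kmer_table"))
    .cpp_kmer_table_lookup(tab$ptr, kmers, tab$k)
}

#' Select bubble-unique k-mers
#'
#' For each bubble, candidate k-mers are those overlapping the variable
#' region in at least one allele's local sequence (allele with `k-1`
#' reference flanks). A k-mer is retained when (i) it occurs at most once
#' within every allele's local sequence, (ii) its total count along all
#' haplotype paths equals the number of paths whose allele contains it (no
#' occurrences outside the bubble region anywhere in the graph), and (iii)
#' its allele-presence pattern is not constant across alleles -- a k-mer
#' present identically in every allele multiplies all HMM states' emissions
#' by the same factor and carries no genotype information. Bubbles may end
#' up with an empty set; they are then genotyped from linkage alone.
#'
#' @param pg a `"pangenome"`.
#' @param graph_tab graph-side `"kmer_table"` from [count_graph_kmers()].
#' @param cap maximum retained k-mers per bubble (bounds emission cost on
#'   long alleles); k-mers closest to the variable region are kept first.
#' @return list with one element per bubble: `kmers` (character) and
#'   `presence` (alleles x k-mers logical matrix).
#' @export
select_unique_kmers <- function(pg, graph_tab, cap = 300L) {
    stopifnot(inherits(pg, "pangenome"), inherits(graph_tab, "kmer_table"))
    k <- pg$k
    N <- length(pg$haplotype_names)
    lapply(pg$bubbles, function(bb) {
        bubble_unique_kmers(bb, pg$reference[[bb$chrom]], k, graph_tab, N, cap)
    })
}

bubble_unique_kmers <- function(bubble, seq_chrom, k, graph_tab, N, cap) {
    left <- substr(seq_chrom, max(1L, bubble$start - (k - 1L)), bubble$start - 1L)
    right <- substr(seq_chrom, bubble$end + 1L,
                    min(nchar(seq_chrom), bubble$end + k - 1L))
    fl_l <- nchar(left)
    nA <- length(bubble$alleles)
    empty <- list(kmers = character(0),
                  presence = matrix(FALSE, nrow = nA, ncol = 0))

    occ <- vector("list", nA)       # per-allele occurrence counts (full local seq)
    cand <- character(0)            # candidates overlapping the variable region
    cand_pos <- integer(0)          # distance rank used when capping
    for (a in seq_len(nA)) {
        loc <- paste0(left, bubble$alleles[a], right)
        km <- .cpp_seq_kmers(loc, k, TRUE)
        valid <- !is.na(km)
        occ[[a]] <- if (any(valid)) table(km[valid]) else integer(0)
        len_a <- nchar(bubble$alleles[a])
        p <- which(valid & seq_along(km) <= fl_l + len_a)
        if (length(p)) {
            newk <- km[p]
            add <- !(newk %in% cand)
            if (any(add)) {
                cand <- c(cand, newk[add])
                cand_pos <- c(cand_pos, p[add])
            }
        }
    }
    if (!length(cand)) return(empty)

    pres_cnt <- vapply(seq_len(nA), function(a) {
        m <- occ[[a]][cand]
        m[is.na(m)] <- 0L
        as.integer(m)
    }, integer(length(cand)))
    pres_cnt <- matrix(pres_cnt, nrow = length(cand))   # kmers x alleles

    keep <- apply(pres_cnt <= 1L, 1, all)               # <=1 within each allele
    presence <- pres_cnt == 1L
    hap_per_allele <- tabulate(bubble$paths + 1L, nbins = nA)
    expected <- as.integer(presence %*% hap_per_allele)
    obs <- kmer_counts(graph_tab, cand)
    keep <- keep & !is.na(obs) & obs == expected        # nothing outside the bubble
    s <- rowSums(presence)
    keep <- keep & s > 0L & s < nA                      # discriminating only

    if (!any(keep)) return(empty)
    idx <- which(keep)[order(cand_pos[keep])]
    idx <- head(idx, cap)
    list(kmers = cand[idx], presence = t(presence[idx, , drop = FALSE]))
}

#' Copy-number vector of a hidden state at a bubble
#'
#' For hidden state (i, j) -- an ordered pair of haplotype paths -- every
#' bubble-unique k-mer is assigned copy number 2 if both chosen paths carry
#' it, 1 if exactly one does, and 0 if neither does. With i = j a k-mer on
#' that path has copy number 2 (the intersection of a path with itself).
#'
#' @param bubble one bubble of a `"pangenome"`.
#' @param kmer_set the bubble's element of [select_unique_kmers()].
#' @param i,j haplotype path indices (1-based; `i == j` allowed).
#' @return integer vector in \{0, 1, 2\}, one entry per k-mer.
#' @export
copy_number_vector <- function(bubble, kmer_set, i, j) {
    ai <- bubble$paths[i] + 1L
    aj <- bubble$paths[j] + 1L
    as.integer(kmer_set$presence[ai, ]) + as.integer(kmer_set$presence[aj, ])
}

#' Estimate the mean k-mer coverage from read counts
#'
#' Uses reference k-mers between bubbles that occur exactly once on every
#' haplotype path and nowhere else (graph count equal to the number of
#' paths): their read counts follow the copy-number-2 count distribution.
#' Counts below `max(2, lambda0/4)` -- where `lambda0` is an initial mean
#' over all nonzero counts -- are treated as error/dropout mass and
#' excluded; the cutoff is refined once.
#'
#' @param pg a `"pangenome"`.
#' @param graph_tab graph-side `"kmer_table"`.
#' @param read_tab read-side `"kmer_table"`.
#' @param max_kmers cap on the number of reference k-mers used.
#' @return estimated mean k-mer coverage (lambda, copy number 2).
#' @export
estimate_mean_coverage <- function(pg, graph_tab, read_tab, max_kmers = 50000L) {
    k <- pg$k
    N <- length(pg$haplotype_names)
    kms <- character(0)
    for (chrom in names(pg$reference)) {
        seq_chrom <- pg$reference[[chrom]]
        bsel <- which(pg$info$chrom == chrom)
        cur <- 1L
        segs <- list()
        for (b in bsel) {
            if (pg$info$start[b] - 1L - cur + 1L >= k)
                segs[[length(segs) + 1L]] <- c(cur, pg$info$start[b] - 1L)
            cur <- pg$info$end[b] + 1L
        }
        if (nchar(seq_chrom) - cur + 1L >= k)
            segs[[length(segs) + 1L]] <- c(cur, nchar(seq_chrom))
        for (sg in segs) {
            km <- .cpp_seq_kmers(substr(seq_chrom, sg[1], sg[2]), k, TRUE)
            kms <- c(kms, km[!is.na(km)])
        }
    }
    if (length(kms) > max_kmers)
        kms <- kms[unique(round(seq(1L, length(kms), length.out = max_kmers)))]
    if (!length(kms))
        stop("cannot estimate mean k-mer coverage: no inter-bubble reference k-mers")
    shared <- kmer_counts(graph_tab, kms) == N
    counts <- kmer_counts(read_tab, kms[shared])
    estimate_lambda_from_counts(counts)
}

#' Estimate lambda from copy-number-2 k-mer counts
#'
#' @param counts integer vector of read k-mer counts for k-mers expected at
#'   copy number 2.
#' @return estimated mean count.
#' @export
estimate_lambda_from_counts <- function(counts) {
    counts <- counts[!is.na(counts)]
    if (!length(counts) || all(counts == 0))
        stop("cannot estimate mean k-mer coverage: all eligible k-mer counts are zero")
    lam0 <- mean(counts[counts > 0])
    sel <- counts >= max(2, lam0 / 4)
    if (!any(sel))
        stop("cannot estimate mean k-mer coverage: no counts above the error cutoff")
    lam <- mean(counts[sel])
    sel <- counts >= max(2, lam / 4)    # one refinement of the cutoff
    mean(counts[sel])
}
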