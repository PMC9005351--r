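# Independent oracles: naive string-based k-mer machinery and brute-force
# HMM enumeration. Deliberately simple and separate from the package's
# implementation paths.

rc_str <- function(s) {
    vapply(s, function(x)
        paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = ""),
        "", USE.NAMES = FALSE)
}

canon_str <- function(kmer) {
    r <- rc_str(kmer)
    ifelse(kmer <= r, kmer, r)
}

# all k-mers of a sequence by sliding window (forward strand)
naive_kmers <- function(seq, k) {
    n <- nchar(seq)
    if (n < k) return(character(0))
    substring(seq, 1:(n - k + 1), k:n)
}

# occurrences of a k-mer in a text, both strands, overlapping allowed
naive_count_occ <- function(text, kmer) {
    km <- naive_kmers(text, nchar(kmer))
    sum(canon_str(km) == canon_str(kmer))
}

# canonical k-mer counts over a set of sequences (the graph-count oracle)
naive_kmer_table <- function(seqs, k) {
    km <- unlist(lapply(seqs, naive_kmers, k = k))
    km <- km[!grepl("[^ACGT]", km)]
    table(canon_str(km))
}

# Brute-force forward-backward: enumerate every assignment of pair states
# over all bubbles; posterior by direct summation. States are indexed
# column-major, s = (j-1)*N + i for pair (i, j), matching matrix layout.
bf_forward_backward <- function(log_emissions, dists, N, r, Ne) {
    M <- length(log_emissions)
    S <- N * N
    Ts <- lapply(dists, function(x) {
        Q <- ls_transition_matrix(N, recomb_distance(max(x, 1), r, Ne))
        kronecker(Q, Q)
    })
    states <- as.matrix(expand.grid(rep(list(seq_len(S)), M)))
    lp <- rep(-log(S), nrow(states))
    for (v in seq_len(M)) lp <- lp + as.vector(log_emissions[[v]])[states[, v]]
    if (M > 1) for (v in 2:M)
        lp <- lp + log(Ts[[v - 1]][cbind(states[, v - 1], states[, v])])
    mx <- max(lp)
    w <- exp(lp - mx)
    posteriors <- lapply(seq_len(M), function(v) {
        p <- vapply(seq_len(S), function(s) sum(w[states[, v] == s]), 0)
        matrix(p / sum(p), N, N)
    })
    list(posteriors = posteriors, loglik = log(sum(w)) + mx)
}

# Single-linkage clustering of variant intervals at reference gap < k:
# the merge oracle for bubble construction.
oracle_clusters <- function(starts, ends, k) {
    o <- order(starts)
    cl <- integer(length(starts))
    cur <- 1L
    cl[o[1]] <- 1L
    run_end <- ends[o[1]]
    for (i in o[-1]) {
        if (starts[i] - run_end - 1L < k) cl[i] <- cur
        else { cur <- cur + 1L; cl[i] <- cur }
        run_end <- max(run_end, ends[i])
    }
    cl
}

# Full haplotype sequence built independently of the package: apply one
# haplotype's non-reference alleles left-to-right into the reference.
naive_hap_seq <- function(seq_chrom, variants, alleles) {
    o <- order(variants$pos)
    cur <- 1L
    parts <- character(0)
    for (i in o) {
        if (alleles[i] == 0L) next
        if (variants$pos[i] > cur)
            parts <- c(parts, substr(seq_chrom, cur, variants$pos[i] - 1L))
        parts <- c(parts, variants$alt[i])
        cur <- variants$pos[i] + nchar(variants$ref[i])
    }
    if (cur <= nchar(seq_chrom))
        parts <- c(parts, substr(seq_chrom, cur, nchar(seq_chrom)))
    paste(parts, collapse = "")
}

# Per-bubble unique-k-mer oracle: candidates from allele local sequences,
# validated by naive substring scans of the explicit path sequences.
oracle_bubble_kmers <- function(pg, b, path_seqs) {
    bb <- pg$bubbles[[b]]
    k <- pg$k
    seq_chrom <- pg$reference[[bb$chrom]]
    left <- substr(seq_chrom, max(1L, bb$start - (k - 1L)), bb$start - 1L)
    right <- substr(seq_chrom, bb$end + 1L,
                    min(nchar(seq_chrom), bb$end + k - 1L))
    locs <- paste0(left, bb$alleles, right)
    cand <- unique(unlist(lapply(seq_along(locs), function(a) {
        km <- naive_kmers(locs[a], k)
        p <- seq_along(km)
        canon_str(km[p <= nchar(left) + nchar(bb$alleles[a])])
    })))
    keep <- character(0)
    presence <- NULL
    for (km in cand) {
        occ_allele <- vapply(locs, naive_count_occ, 0, kmer = km)
        if (any(occ_allele > 1)) next
        expected <- sum(occ_allele[bb$paths + 1L])
        total <- sum(vapply(path_seqs, naive_count_occ, 0, kmer = km))
        if (total != expected) next
        pres <- occ_allele == 1
        if (all(pres) || !any(pres)) next      # non-discriminating
        keep <- c(keep, km)
        presence <- cbind(presence, pres)
    }
    list(kmers = keep, presence = presence)
}

expect_same_kmer_set <- function(kset, oracle) {
    expect_setequal(kset$kmers, oracle$kmers)
    if (length(kset$kmers)) {
        m <- match(kset$kmers, oracle$kmers)
        expect_equal(unname(kset$presence), unname(oracle$presence[, m, drop = FALSE]),
                     ignore_attr = TRUE)
    }
}
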