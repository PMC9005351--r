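# Bubble construction: panel variants whose reference-affected intervals are
# separated by fewer than k reference bases are transitively merged into one
# bubble; the bubble's alleles are the distinct haplotype sequences over the
# merged span, with bookkeeping that maps every bubble allele back to the
# alleles of each source variant.

#' Build a pangenome of merged bubbles from a haplotype panel
#'
#' Variants closer than `k` reference bases (strictly: separated by fewer
#' than `k` bases; a gap of exactly `k` stays separate) are merged via
#' single-linkage into one bubble, because a k-mer could otherwise span two
#' sites and confound their evidence. Bubble alleles are the distinct
#' sequences spelled by the haplotype paths across the merged span; allele 0
#' is always the reference sequence. Bubbles with more than two alleles are
#' flagged complex.
#'
#' @param panel a `"panel"` object from [read_panel()].
#' @param k k-mer length that defines the merge distance (default 31; must
#'   be odd so that no k-mer is its own reverse complement).
#' @return an object of class `"pangenome"`: reference, k, haplotype names,
#'   and an ordered list of bubbles. Each bubble holds `chrom`, `start`,
#'   `end` (1-based inclusive reference span), `alleles` (character vector,
#'   element `a+1` is bubble allele `a`), `paths` (0-based allele index per
#'   haplotype), `tuples` (allele x source-variant matrix of source allele
#'   indices) and `src` (source variant data frame).
#' @export
build_bubbles <- function(panel, k = 31L) {
    stopifnot(inherits(panel, "panel"))
    k <- as.integer(k)
    if (k < 2L) stop("k must be >= 2")
    if (k %% 2L == 0L) stop("k must be odd (even k admits palindromic k-mers)")
    N <- length(panel$haplotype_names)
    bubbles <- list()
    for (chrom in unique(panel$variants$chrom)) {
        idx <- which(panel$variants$chrom == chrom)
        vv <- panel$variants[idx, , drop = FALSE]
        vv$pos <- as.integer(vv$pos)
        hh <- panel$haps[idx, , drop = FALSE]
        o <- order(vv$pos)
        vv <- vv[o, , drop = FALSE]; hh <- hh[o, , drop = FALSE]
        aff_s <- vv$pos
        aff_e <- vv$pos + nchar(vv$ref) - 1L
        # single-linkage clustering on reference gaps < k
        cl <- integer(nrow(vv)); cur <- 1L; cl[1] <- 1L
        run_end <- aff_e[1]
        for (i in seq_len(nrow(vv))[-1]) {
            gap <- aff_s[i] - run_end - 1L
            if (gap < k) { cl[i] <- cur } else { cur <- cur + 1L; cl[i] <- cur }
            run_end <- max(run_end, aff_e[i])
        }
        seq_chrom <- panel$reference[[chrom]]
        for (ci in seq_len(cur)) {
            sel <- which(cl == ci)
            bubbles[[length(bubbles) + 1L]] <-
                make_bubble(chrom, seq_chrom, vv[sel, , drop = FALSE],
                            hh[sel, , drop = FALSE], N)
        }
    }
    info <- data.frame(
        chrom = vapply(bubbles, `[[`, "", "chrom"),
        start = vapply(bubbles, `[[`, 0L, "start"),
        end = vapply(bubbles, `[[`, 0L, "end"),
        n_alleles = vapply(bubbles, function(b) length(b$alleles), 0L),
        complex = vapply(bubbles, function(b) b$is_complex, FALSE),
        stringsAsFactors = FALSE
    )
    structure(list(reference = panel$reference, k = k,
                   haplotype_names = panel$haplotype_names,
                   bubbles = bubbles, info = info),
              class = "pangenome")
}

# Build one bubble from a cluster of sorted variants. Haplotype sequences are
# spelled by substituting each haplotype's non-reference alleles into the
# span; allele 0 is forced to be the reference sequence.
make_bubble <- function(chrom, seq_chrom, vars, haps, N) {
    span_s <- min(vars$pos)
    span_e <- max(vars$pos + nchar(vars$ref) - 1L)
    ref_span <- substr(seq_chrom, span_s, span_e)
    alleles <- ref_span
    tuples <- matrix(0L, nrow = 1L, ncol = nrow(vars))
    paths <- integer(N)
    for (h in seq_len(N)) {
        res <- spell_haplotype(seq_chrom, span_s, span_e, vars, haps[, h])
        hit <- match(res$seq, alleles)
        if (is.na(hit)) {
            alleles <- c(alleles, res$seq)
            tuples <- rbind(tuples, res$applied)
            hit <- length(alleles)
        }
        paths[h] <- hit - 1L
    }
    list(chrom = chrom, start = span_s, end = span_e,
         alleles = alleles, paths = paths, tuples = tuples,
         src = vars, is_complex = length(alleles) > 2L)
}

# Substitute the non-reference alleles of one haplotype into the reference
# span [span_s, span_e]. Overlapping non-reference variants on the same
# haplotype cannot be spelled; the later one is an error.
spell_haplotype <- function(seq_chrom, span_s, span_e, vars, allele) {
    applied <- as.integer(allele)
    cur <- span_s
    parts <- character(0)
    for (i in seq_len(nrow(vars))) {
        if (allele[i] == 0L) next
        vs <- vars$pos[i]
        ve <- vs + nchar(vars$ref[i]) - 1L
        if (vs < cur)
            stop(sprintf("overlapping non-reference variants on one haplotype at %s:%d",
                         vars$chrom[i], vs))
        if (vs > cur) parts <- c(parts, substr(seq_chrom, cur, vs - 1L))
        parts <- c(parts, vars$alt[i])
        cur <- ve + 1L
    }
    if (cur <= span_e) parts <- c(parts, substr(seq_chrom, cur, span_e))
    list(seq = paste(parts, collapse = ""), applied = applied)
}

#' Full haplotype path sequences through the pangenome
#'
#' Substitutes each haplotype's bubble alleles into the reference, yielding
#' the complete path sequence per haplotype and chromosome.
#'
#' @param pg a `"pangenome"` object.
#' @return list (per chromosome) of character vectors (one per haplotype).
#' @export
haplotype_path_seqs <- function(pg) {
    N <- length(pg$haplotype_names)
    out <- list()
    for (chrom in names(pg$reference)) {
        bsel <- which(pg$info$chrom == chrom)
        seq_chrom <- pg$reference[[chrom]]
        paths <- character(N)
        for (h in seq_len(N)) {
            cur <- 1L
            parts <- character(0)
            for (b in bsel) {
                bb <- pg$bubbles[[b]]
                if (bb$start > cur) parts <- c(parts, substr(seq_chrom, cur, bb$start - 1L))
                parts <- c(parts, bb$alleles[bb$paths[h] + 1L])
                cur <- bb$end + 1L
            }
            if (cur <= nchar(seq_chrom)) parts <- c(parts, substr(seq_chrom, cur, nchar(seq_chrom)))
            paths[h] <- paste(parts, collapse = "")
        }
        out[[chrom]] <- paths
    }
    out
}

#' Decompose a bubble genotype into source-variant genotypes
#'
#' Each bubble allele maps to one allele of every source variant via the
#' bookkeeping recorded at construction; the unordered bubble allele pair is
#' translated accordingly.
#'
#' @param bubble one bubble of a `"pangenome"`.
#' @param genotype integer vector of two 0-based bubble allele indices
#'   (unordered).
#' @return data frame with one row per source variant: `src_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `a1`, `a2` (sorted source-allele pair).
#' @export
decompose_genotypes <- function(bubble, genotype) {
    stopifnot(length(genotype) == 2L)
    a <- as.integer(genotype) + 1L
    if (any(a < 1L) || any(a > nrow(bubble$tuples)))
        stop("genotype allele index out of range for bubble")
    g1 <- bubble$tuples[a[1], ]
    g2 <- bubble$tuples[a[2], ]
    data.frame(src_id = bubble$src$src_id,
               chrom = bubble$src$chrom, pos = bubble$src$pos,
               ref = bubble$src$ref, alt = bubble$src$alt,
               a1 = pmin(g1, g2), a2 = pmax(g1, g2),
               stringsAsFactors = FALSE)
}

#' @export
print.pangenome <- function(x, ...) {
    cat(sprintf("Pangenome: %d bubbles on %d chromosome(s), %d haplotype paths, k=%d\n",
                length(x$bubbles), length(unique(x$info$chrom)),
                length(x$haplotype_names), x$k))
    cat(sprintf("  complex (multiallelic) bubbles: %d (%.1f%%)\n",
                sum(x$info$complex), 100 * mean(x$info$complex)))
    invisible(x)
}
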