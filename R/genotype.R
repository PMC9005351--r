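#' Genotype a sample from raw reads and a haplotype panel
#'
#' End-to-end genome inference: counts all k-mers along the panel haplotype
#' paths, selects bubble-unique k-mers, counts them in the sample reads,
#' estimates the mean k-mer coverage, and runs the pair-of-haplotypes HMM
#' per chromosome. Deterministic given inputs and parameters; chromosomes
#' are independent chains, so results do not depend on processing order.
#'
#' @param pg a `"pangenome"` from [build_bubbles()].
#' @param reads FASTQ/FASTA path or character vector of read sequences.
#' @param r recombination rate in Morgans/Mb (0.0126 = 1.26 cM/Mb).
#' @param Ne effective population size.
#' @param kmer_cap maximum unique k-mers per bubble.
#' @param lambda mean k-mer coverage; estimated from the data when `NULL`.
#' @param p_geom geometric error parameter; derived from `lambda` when `NULL`.
#' @param gq_cap maximum reported genotype quality.
#' @param verbose print progress and fitted parameters.
#' @return an object of class `"genotype_fit"`; see [print.genotype_fit()],
#'   [summary.genotype_fit()], [coef.genotype_fit()],
#'   [write_genotyped_vcf()]. `$calls` holds one row per bubble with the
#'   called genotype and quality; `$likelihoods` the per-bubble genotype
#'   likelihood vectors; `$posteriors` the per-bubble state posteriors.
#' @export
genotype_sample <- function(pg, reads, r = 0.0126, Ne = 25000, kmer_cap = 300L,
                            lambda = NULL, p_geom = NULL, gq_cap = 10000L,
                            verbose = FALSE) {
    stopifnot(inherits(pg, "pangenome"))
    N <- length(pg$haplotype_names)
    say <- function(...) if (verbose) message(sprintf(...))

    say("counting k-mers along %d haplotype paths ...", N)
    graph_tab <- count_graph_kmers(pg)
    say("selecting bubble-unique k-mers for %d bubbles ...", length(pg$bubbles))
    ksets <- select_unique_kmers(pg, graph_tab, cap = kmer_cap)
    say("counting graph k-mers in reads ...")
    read_tab <- count_read_kmers(reads, graph_tab)
    if (is.null(lambda))
        lambda <- estimate_mean_coverage(pg, graph_tab, read_tab)
    model <- emission_model(lambda, p_geom)
    say("mean k-mer coverage lambda = %.2f; geometric p = %.4f",
        model$lambda, model$p_geom)

    nb <- length(pg$bubbles)
    posteriors <- vector("list", nb)
    loglik <- 0
    for (chrom in unique(pg$info$chrom)) {
        bsel <- which(pg$info$chrom == chrom)
        logE <- lapply(bsel, function(b) {
            counts <- kmer_counts(read_tab, ksets[[b]]$kmers)
            bubble_emission_matrix(pg$bubbles[[b]], ksets[[b]], counts, model, N)
        })
        gaps <- if (length(bsel) > 1)
            pg$info$start[bsel[-1]] - pg$info$end[bsel[-length(bsel)]] - 1L
        else integer(0)
        fb <- forward_backward(logE, gaps, N, r = r, Ne = Ne)
        posteriors[bsel] <- fb$posteriors
        loglik <- loglik + fb$loglik
    }

    gl <- lapply(seq_len(nb), function(b)
        genotype_likelihoods(pg$bubbles[[b]], posteriors[[b]], gq_cap = gq_cap))
    n_kmers <- vapply(ksets, function(x) length(x$kmers), 0L)
    calls <- data.frame(
        bubble = seq_len(nb),
        chrom = pg$info$chrom, start = pg$info$start, end = pg$info$end,
        n_alleles = pg$info$n_alleles, complex = pg$info$complex,
        n_kmers = n_kmers,
        gt = vapply(gl, function(g) paste(g$genotype, collapse = "/"), ""),
        gq = vapply(gl, `[[`, 0L, "gq"),
        stringsAsFactors = FALSE
    )
    say("%d/%d bubbles have no informative k-mers (genotyped from linkage)",
        sum(n_kmers == 0), nb)
    structure(list(calls = calls,
                   likelihoods = lapply(gl, `[[`, "likelihoods"),
                   posteriors = posteriors,
                   lambda = model$lambda, p_geom = model$p_geom,
                   r = r, Ne = Ne, loglik = loglik,
                   pangenome = pg),
              class = "genotype_fit")
}

#' @rdname genotype_sample
#' @param x,object a `"genotype_fit"`.
#' @param ... unused.
#' @export
print.genotype_fit <- function(x, ...) {
    cat(sprintf("Pangenome genotyping fit: %d bubbles, %d haplotype paths\n",
                nrow(x$calls), length(x$pangenome$haplotype_names)))
    cat(sprintf("  mean k-mer coverage lambda = %.2f (geometric p = %.4f)\n",
                x$lambda, x$p_geom))
    cat(sprintf("  log-likelihood = %.2f\n", x$loglik))
    het <- vapply(strsplit(x$calls$gt, "/"), function(g) g[1] != g[2], FALSE)
    cat(sprintf("  calls: %d het, %d hom (%d non-ref), median GQ %d\n",
                sum(het), sum(!het),
                sum(x$calls$gt != "0/0"), as.integer(stats::median(x$calls$gq))))
    invisible(x)
}

#' @rdname genotype_sample
#' @export
summary.genotype_fit <- function(object, ...) {
    cls <- ifelse(object$calls$complex, "complex", "biallelic")
    tab <- do.call(rbind, lapply(split(seq_len(nrow(object$calls)), cls), function(i) {
        data.frame(n = length(i),
                   no_kmers = sum(object$calls$n_kmers[i] == 0),
                   nonref = sum(object$calls$gt[i] != "0/0"),
                   median_gq = as.integer(stats::median(object$calls$gq[i])),
                   gq200 = sum(object$calls$gq[i] >= 200))
    }))
    structure(list(lambda = object$lambda, p_geom = object$p_geom,
                   loglik = object$loglik, by_class = tab),
              class = "summary.genotype_fit")
}

#' @export
print.summary.genotype_fit <- function(x, ...) {
    cat(sprintf("lambda = %.2f, geometric p = %.4f, log-likelihood = %.2f\n",
                x$lambda, x$p_geom, x$loglik))
    cat("per bubble class (gq200 = calls with GQ >= 200):\n")
    print(x$by_class)
    invisible(x)
}

#' @rdname genotype_sample
#' @export
coef.genotype_fit <- function(object, ...) {
    c(lambda = object$lambda, p_geom = object$p_geom,
      r = object$r, Ne = object$Ne)
}

#' Decompose all bubble calls to source-variant genotypes
#'
#' Translates each bubble's genotype and likelihoods back to its source
#' (input VCF) variants. Source-variant genotype likelihoods pool the
#' bubble-genotype likelihoods that map to the same source genotype.
#'
#' @param fit a `"genotype_fit"`.
#' @return data frame with one row per (bubble, source variant): variant
#'   key columns, called genotype `a1/a2`, `gq`, and `gl` (list column of
#'   3-genotype likelihood vectors).
#' @export
decompose_calls <- function(fit) {
    stopifnot(inherits(fit, "genotype_fit"))
    pg <- fit$pangenome
    out <- vector("list", length(pg$bubbles))
    for (b in seq_along(pg$bubbles)) {
        bb <- pg$bubbles[[b]]
        gt <- as.integer(strsplit(fit$calls$gt[b], "/")[[1]])
        dec <- decompose_genotypes(bb, gt)
        lik <- fit$likelihoods[[b]]
        pairs <- genotype_pair_order(length(bb$alleles))
        gl <- lapply(seq_len(nrow(bb$src)), function(s) {
            m <- bb$tuples[, s]
            key <- sprintf("%d/%d", pmin(m[pairs[, 1] + 1L], m[pairs[, 2] + 1L]),
                           pmax(m[pairs[, 1] + 1L], m[pairs[, 2] + 1L]))
            v <- setNames(numeric(3), c("0/0", "0/1", "1/1"))
            sums <- tapply(lik, key, sum)
            v[names(sums)] <- sums
            v / sum(v)
        })
        gq <- vapply(seq_along(gl), function(s) {
            p <- gl[[s]][sprintf("%d/%d", dec$a1[s], dec$a2[s])]
            if (p >= 1) 10000L else as.integer(min(10000, round(-10 * log10(1 - p))))
        }, 0L)
        dec$bubble <- b
        dec$gq <- gq
        dec$gl <- I(gl)
        out[[b]] <- dec
    }
    do.call(rbind, out)
}
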