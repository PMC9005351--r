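# Evaluation statistics for genotype callsets: weighted genotype
# concordance, genotype-aware precision/recall (with an adjusted mode that
# does not penalize variants absent from the genotyper's input panel),
# trio Mendelian consistency, cohort reliability filters and
# Hardy-Weinberg tests.

norm_gt <- function(gt) {
    gt[gt %in% c("./.", ".", ".|.")] <- NA_character_
    vapply(strsplit(gsub("|", "/", gt, fixed = TRUE), "/", fixed = TRUE),
           function(a) {
               if (length(a) != 2L || anyNA(suppressWarnings(as.integer(a))))
                   return(NA_character_)
               a <- sort(as.integer(a))
               sprintf("%d/%d", a[1], a[2])
           }, "")
}

#' Weighted genotype concordance (wGC)
#'
#' Mean of the per-truth-genotype-class concordances over the classes 0/0,
#' 0/1 and 1/1, putting equal emphasis on the ability to detect all three
#' genotypes regardless of their frequencies. Untyped calls count as
#' discordant within their truth class; classes absent from the truth are
#' excluded from the mean.
#'
#' @param truth,called character vectors of genotypes ("a/b"; allele order
#'   and `|`/`/` separators are normalized; NA or "./." means untyped).
#' @return wGC in percent.
#' @export
weighted_genotype_concordance <- function(truth, called) {
    stopifnot(length(truth) == length(called))
    truth <- norm_gt(truth); called <- norm_gt(called)
    ok <- !is.na(truth)
    truth <- truth[ok]; called <- called[ok]
    if (!length(truth)) return(NA_real_)
    per_class <- vapply(unique(truth), function(cl) {
        i <- truth == cl
        mean(!is.na(called[i]) & called[i] == cl)
    }, 0)
    100 * mean(per_class)
}

#' Plain genotype concordance
#'
#' Fraction of variants whose called genotype equals the truth genotype
#' (untyped counted discordant), in percent.
#'
#' @inheritParams weighted_genotype_concordance
#' @export
genotype_concordance <- function(truth, called) {
    truth <- norm_gt(truth); called <- norm_gt(called)
    ok <- !is.na(truth)
    100 * mean(!is.na(called[ok]) & called[ok] == truth[ok])
}

#' Genotype-aware precision, recall and F score
#'
#' A truth variant is a positive when its truth genotype is non-reference; a
#' call counts as correct when it is non-reference and matches the truth
#' genotype exactly. The adjusted recall removes truth variants absent from
#' the genotyper's input panel from the denominator, so a method is not
#' penalized for variants it could never genotype.
#'
#' @inheritParams weighted_genotype_concordance
#' @param in_panel logical vector: is the truth variant present in the
#'   genotyper's input panel? Defaults to all `TRUE`.
#' @return list with `precision`, `recall`, `f`, `recall_adjusted`,
#'   `f_adjusted` (proportions in 0..1).
#' @export
genotype_precision_recall <- function(truth, called, in_panel = NULL) {
    truth <- norm_gt(truth); called <- norm_gt(called)
    if (is.null(in_panel)) in_panel <- rep(TRUE, length(truth))
    stopifnot(length(truth) == length(called), length(in_panel) == length(truth))
    pos <- !is.na(truth) & truth != "0/0"
    called_pos <- !is.na(called) & called != "0/0"
    correct <- pos & called_pos & called == truth
    precision <- if (sum(called_pos)) sum(correct) / sum(called_pos) else NA_real_
    recall <- if (sum(pos)) sum(correct) / sum(pos) else NA_real_
    recall_adj <- if (sum(pos & in_panel)) sum(correct & in_panel) / sum(pos & in_panel) else NA_real_
    f <- function(p, r) if (is.na(p) || is.na(r) || p + r == 0) NA_real_ else 2 * p * r / (p + r)
    list(precision = precision, recall = recall, f = f(precision, recall),
         recall_adjusted = recall_adj, f_adjusted = f(precision, recall_adj))
}

#' Trio Mendelian consistency
#'
#' A trio is evaluated only when its three genotypes are not all identical
#' (a trio that is all 0/0, all 0/1 or all 1/1 is uninformative and
#' excluded); trios with an untyped member are excluded too. A trio is
#' consistent when the child's alleles can be drawn one from each parent.
#'
#' @param child,mother,father genotype vectors ("a/b").
#' @return list with `fraction` (consistent among evaluated), `evaluated`
#'   and `consistent` logical vectors.
#' @export
mendelian_consistency <- function(child, mother, father) {
    child <- norm_gt(child); mother <- norm_gt(mother); father <- norm_gt(father)
    n <- length(child)
    stopifnot(length(mother) == n, length(father) == n)
    evaluated <- !is.na(child) & !is.na(mother) & !is.na(father) &
        !(child == mother & child == father)
    consistent <- rep(NA, n)
    for (i in which(evaluated)) {
        ca <- as.integer(strsplit(child[i], "/")[[1]])
        ma <- as.integer(strsplit(mother[i], "/")[[1]])
        fa <- as.integer(strsplit(father[i], "/")[[1]])
        consistent[i] <- (ca[1] %in% ma && ca[2] %in% fa) ||
                         (ca[2] %in% ma && ca[1] %in% fa)
    }
    frac <- if (any(evaluated)) mean(consistent[evaluated]) else NA_real_
    list(fraction = frac, evaluated = evaluated, consistent = consistent)
}

#' Cohort reliability filters
#'
#' The five per-variant filters used to distill a strict high-confidence
#' set from a genotyped cohort:
#' \describe{
#'   \item{ac0_fail}{allele frequency 0.0 across all cohort samples}
#'   \item{mendel_fail}{fraction of Mendelian-consistent trios below 90%
#'     (trios with three identical genotypes are not evaluated)}
#'   \item{gq_fail}{genotype quality below 200 in more than 5 samples}
#'   \item{self_fail}{genotype concordance across re-genotyped panel
#'     samples below 90%}
#'   \item{nonref_fail}{genotyped 0/0 across all panel samples}
#' }
#' The strict set contains the variants passing all five.
#'
#' @param gt variants x cohort-samples genotype matrix ("a/b" strings).
#' @param gq variants x cohort-samples genotype quality matrix.
#' @param trios data frame with columns `child`, `mother`, `father` naming
#'   (or indexing) cohort sample columns.
#' @param panel_gt variants x panel-samples matrix of re-genotyped panel
#'   sample genotypes.
#' @param panel_truth variants x panel-samples matrix of the panel's own
#'   genotypes (from its haplotypes).
#' @param gq_threshold,gq_max_samples,mendel_min,self_min filter parameters
#'   (defaults: 200, 5, 0.9, 0.9).
#' @return data frame of logical flags plus `strict`.
#' @export
cohort_filters <- function(gt, gq, trios, panel_gt, panel_truth,
                           gq_threshold = 200, gq_max_samples = 5,
                           mendel_min = 0.9, self_min = 0.9) {
    nv <- nrow(gt)
    stopifnot(nrow(gq) == nv, nrow(panel_gt) == nv, nrow(panel_truth) == nv)
    gtn <- matrix(norm_gt(gt), nrow = nv)
    alt_count <- function(g) {
        a <- strsplit(g, "/", fixed = TRUE)
        vapply(a, function(x) sum(as.integer(x) > 0L), 0L)
    }
    ac <- apply(gtn, 1, function(g) sum(alt_count(g[!is.na(g)])))
    ac0_fail <- ac == 0L

    mendel_frac <- rep(NA_real_, nv)
    cons <- matrix(NA, nv, nrow(trios))
    evaluated <- matrix(FALSE, nv, nrow(trios))
    for (t in seq_len(nrow(trios))) {
        mc <- mendelian_consistency(gt[, trios$child[t]], gt[, trios$mother[t]],
                                    gt[, trios$father[t]])
        cons[, t] <- mc$consistent
        evaluated[, t] <- mc$evaluated
    }
    n_eval <- rowSums(evaluated)
    n_cons <- rowSums(cons & evaluated, na.rm = TRUE)
    mendel_frac[n_eval > 0] <- n_cons[n_eval > 0] / n_eval[n_eval > 0]
    mendel_fail <- !is.na(mendel_frac) & mendel_frac < mendel_min

    gq_fail <- rowSums(gq < gq_threshold, na.rm = TRUE) > gq_max_samples

    pg <- matrix(norm_gt(panel_gt), nrow = nv)
    pt <- matrix(norm_gt(panel_truth), nrow = nv)
    self_conc <- rowMeans(!is.na(pg) & !is.na(pt) & pg == pt)
    self_fail <- self_conc < self_min

    nonref_fail <- apply(pg, 1, function(g) all(!is.na(g) & g == "0/0"))

    out <- data.frame(ac0_fail = ac0_fail, mendel_fail = mendel_fail,
                      gq_fail = gq_fail, self_fail = self_fail,
                      nonref_fail = nonref_fail)
    out$strict <- !(out$ac0_fail | out$mendel_fail | out$gq_fail |
                    out$self_fail | out$nonref_fail)
    out$mendel_fraction <- mendel_frac
    out$self_concordance <- self_conc
    out
}

#' Hardy-Weinberg equilibrium test
#'
#' One-degree-of-freedom chi-square test of biallelic genotype counts
#' against Hardy-Weinberg proportions, with Benjamini-Hochberg correction
#' across variants.
#'
#' @param counts matrix or data frame with columns n00, n01, n11 (genotype
#'   counts per variant).
#' @param alpha significance level for the BH-adjusted deviation flag.
#' @return data frame with `chisq`, `p`, `p_adj`, `deviates`.
#' @export
hwe_test <- function(counts, alpha = 0.05) {
    counts <- as.matrix(counts)
    stopifnot(ncol(counts) == 3L)
    n <- rowSums(counts)
    p_hat <- (2 * counts[, 1] + counts[, 2]) / (2 * n)
    expd <- cbind(n * p_hat^2, 2 * n * p_hat * (1 - p_hat), n * (1 - p_hat)^2)
    chisq <- rowSums((counts - expd)^2 / ifelse(expd > 0, expd, NA), na.rm = TRUE)
    fixed <- p_hat %in% c(0, 1)       # monomorphic: no test
    chisq[fixed] <- 0
    p <- pchisq(chisq, df = 1, lower.tail = FALSE)
    p_adj <- p.adjust(p, method = "BH")
    data.frame(chisq = chisq, p = p, p_adj = p_adj,
               deviates = p_adj < alpha)
}

#' Compare a called VCF against truth genotypes
#'
#' Joins truth and call records on the variant key (chrom, pos, ref, alt)
#' and returns a per-variant comparison table with stratification columns.
#'
#' @param truth data frame with chrom, pos, ref, alt and truth alleles
#'   a1/a2 (as written by [simulate_dataset()]'s truth TSV), or a VCF path
#'   with a GT field.
#' @param calls data frame from [read_genotyped_vcf()] or a VCF path.
#' @param repeats optional BED data frame (chrom, start0, end) of repeat
#'   regions for the repeat stratum.
#' @return data frame with key columns, `truth_gt`, `called_gt`, `gq`,
#'   `type`, `size_class`, `complex`, `in_repeat`.
#' @export
compare_genotypes <- function(truth, calls, repeats = NULL) {
    if (is.character(truth) && length(truth) == 1L) {
        tv <- read_genotyped_vcf(truth)
        g <- norm_gt(tv$gt)
        truth <- data.frame(chrom = tv$chrom, pos = tv$pos, ref = tv$ref,
                            alt = tv$alt, stringsAsFactors = FALSE)
        truth$a1 <- as.integer(sub("/.*", "", g))
        truth$a2 <- as.integer(sub(".*/", "", g))
    }
    if (is.character(calls) && length(calls) == 1L)
        calls <- read_genotyped_vcf(calls)
    key <- function(d) sprintf("%s:%d:%s>%s", d$chrom, d$pos, d$ref, d$alt)
    m <- match(key(truth), key(calls))
    cls <- classify_variant(truth$ref, truth$alt)
    out <- data.frame(chrom = truth$chrom, pos = truth$pos, ref = truth$ref,
                      alt = truth$alt,
                      truth_gt = sprintf("%d/%d", truth$a1, truth$a2),
                      called_gt = norm_gt(calls$gt[m]),
                      gq = calls$gq[m],
                      type = cls$type, size_class = cls$size_class,
                      complex = calls$complex[m],
                      stringsAsFactors = FALSE)
    out$in_repeat <- if (!is.null(truth$in_repeat)) truth$in_repeat
    else if (!is.null(repeats)) {
        vapply(seq_len(nrow(out)), function(i)
            any(repeats[[1]] == out$chrom[i] & repeats[[2]] < out$pos[i] &
                repeats[[3]] >= out$pos[i]), FALSE)
    } else NA
    out
}

#' Stratified evaluation report
#'
#' Computes wGC, plain concordance and genotype-aware precision/recall/F
#' per (type, size class, region class) stratum and overall.
#'
#' @param comparison data frame from [compare_genotypes()].
#' @return data frame with one row per stratum.
#' @export
evaluation_report <- function(comparison) {
    strata <- list(overall = rep(TRUE, nrow(comparison)))
    for (ty in unique(comparison$type))
        strata[[ty]] <- comparison$type == ty
    for (sc in unique(comparison$size_class))
        strata[[sc]] <- comparison$size_class == sc
    if (!all(is.na(comparison$complex))) {
        strata[["complex"]] <- !is.na(comparison$complex) & comparison$complex
        strata[["biallelic"]] <- !is.na(comparison$complex) & !comparison$complex
    }
    if (!all(is.na(comparison$in_repeat))) {
        strata[["repeat"]] <- isTRUE_vec(comparison$in_repeat)
        strata[["non-repeat"]] <- !isTRUE_vec(comparison$in_repeat)
    }
    do.call(rbind, lapply(names(strata), function(nm) {
        i <- strata[[nm]]
        if (!sum(i)) return(NULL)
        pr <- genotype_precision_recall(comparison$truth_gt[i],
                                        comparison$called_gt[i])
        data.frame(stratum = nm, n = sum(i),
                   wgc = weighted_genotype_concordance(comparison$truth_gt[i],
                                                       comparison$called_gt[i]),
                   concordance = genotype_concordance(comparison$truth_gt[i],
                                                      comparison$called_gt[i]),
                   precision = pr$precision, recall = pr$recall, f = pr$f,
                   stringsAsFactors = FALSE)
    }))
}

isTRUE_vec <- function(x) !is.na(x) & x
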