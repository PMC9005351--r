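# Genotyping HMM. Hidden states at each bubble are ordered pairs (i, j) of
# panel haplotype paths (N^2 states, i = j allowed). Transitions follow the
# Li-Stephens haplotype copying model per haplotype; emissions are products
# of per-k-mer count probabilities given the state's copy-number vector.
# The forward-backward recursion uses Rabiner-style per-column scaling.

#' Emission model for k-mer counts
#'
#' Counts of a k-mer at copy number 2 follow Poisson(lambda); at copy number
#' 1, Poisson(lambda/2); at copy number 0 (erroneous k-mers) a geometric
#' distribution on counts c >= 0 with pmf `p (1-p)^c`. By default
#' `p = 1 / (1 + lambda/40)`: a k-mer absent from the genome is observed
#' only through sequencing errors that recreate it, so its expected count
#' (here lambda/40, i.e. 2.5% of the diploid coverage) must be a small
#' fraction of the coverage; a heavier error tail lets genuinely low
#' allele-depth draws at heterozygous sites be explained away as error
#' k-mers and flips calls toward homozygous.
#'
#' @param lambda mean k-mer coverage at copy number 2 (> 0).
#' @param p_geom geometric parameter for copy number 0, in (0, 1]; default
#'   derived from `lambda`.
#' @return object of class `"emission_model"`.
#' @export
emission_model <- function(lambda, p_geom = NULL) {
    stopifnot(is.numeric(lambda), lambda > 0)
    if (is.null(p_geom)) p_geom <- 1 / (1 + lambda / 40)
    stopifnot(p_geom > 0, p_geom <= 1)
    structure(list(lambda = lambda, p_geom = p_geom), class = "emission_model")
}

#' @export
print.emission_model <- function(x, ...) {
    cat(sprintf("k-mer count emission model: lambda=%.3f (cn2), lambda/2=%.3f (cn1), geometric p=%.4f (cn0)\n",
                x$lambda, x$lambda / 2, x$p_geom))
    invisible(x)
}

#' Log-probability of observed k-mer counts given copy numbers
#'
#' @param model an `"emission_model"`.
#' @param counts observed read counts (non-negative integers).
#' @param cn copy numbers in \{0, 1, 2\}, same length as `counts`.
#' @return vector of per-k-mer log probabilities.
#' @export
kmer_count_logpmf <- function(model, counts, cn) {
    stopifnot(length(counts) == length(cn))
    if (any(counts < 0)) stop("negative k-mer counts are invalid")
    out <- numeric(length(counts))
    out[cn == 0L] <- dgeom(counts[cn == 0L], prob = model$p_geom, log = TRUE)
    out[cn == 1L] <- dpois(counts[cn == 1L], lambda = model$lambda / 2, log = TRUE)
    out[cn == 2L] <- dpois(counts[cn == 2L], lambda = model$lambda, log = TRUE)
    out
}

#' Emission log-probability of a state
#'
#' k-mer counts are assumed independent given the copy-number vector; an
#' empty k-mer set yields log-probability 0 (probability 1, uninformative
#' bubble).
#'
#' @param model an `"emission_model"`.
#' @param counts observed counts for the bubble's unique k-mers.
#' @param cn copy-number vector of the state (see [copy_number_vector()]).
#' @export
emission_logprob <- function(model, counts, cn) {
    if (!length(counts)) return(0)
    sum(kmer_count_logpmf(model, counts, cn))
}

# Per-bubble emission log-likelihoods over unordered allele pairs, expanded
# to the N x N state matrix through the haplotype paths. Emission depends on
# the state only through its allele pair.
bubble_emission_matrix <- function(bubble, kmer_set, counts, model, N) {
    nA <- length(bubble$alleles)
    E <- matrix(0, nA, nA)
    if (length(kmer_set$kmers)) {
        for (a in seq_len(nA)) {
            for (b in a:nA) {
                cn <- as.integer(kmer_set$presence[a, ]) +
                      as.integer(kmer_set$presence[b, ])
                E[a, b] <- E[b, a] <- emission_logprob(model, counts, cn)
            }
        }
    }
    ai <- bubble$paths + 1L
    E[ai, ai, drop = FALSE]     # N x N log-emissions for states (i, j)
}

#' Li-Stephens recombination distance
#'
#' `d = x * 1e-6 * 4 * r * Ne` for a reference gap of `x` bp, recombination
#' rate `r` and effective population size `Ne`. `r` is expressed in
#' Morgans/Mb so that `4 * r * Ne` is the standard population-scaled
#' recombination density; the default 0.0126 Morgans/Mb is the human
#' genome-wide average of 1.26 cM/Mb.
#'
#' @param x distance in bp between consecutive bubbles (>= 0).
#' @param r recombination rate in Morgans/Mb (0.0126 = 1.26 cM/Mb).
#' @param Ne effective population size.
#' @export
recomb_distance <- function(x, r = 0.0126, Ne = 25000) {
    stopifnot(all(x >= 0), r > 0, Ne > 0)
    x * 1e-6 * 4 * r * Ne
}

#' Per-haplotype Li-Stephens transition matrix
#'
#' With `p_r = (1 - exp(-d/N)) / N` and `q_r = exp(-d/N) + p_r`, the
#' probability of copying from the same haplotype is `q_r` and from any
#' particular other haplotype `p_r`; rows sum to 1 for any d and N. The
#' pair-state transition probability factorizes as the product of the two
#' per-haplotype terms.
#'
#' @param N number of haplotype paths.
#' @param d recombination distance from [recomb_distance()].
#' @return N x N matrix Q with `Q[k, i] = P(haplotype i | haplotype k)`.
#' @export
ls_transition_matrix <- function(N, d) {
    stopifnot(N >= 2, d >= 0)
    p_r <- (1 - exp(-d / N)) / N
    q_r <- exp(-d / N) + p_r
    Q <- matrix(p_r, N, N)
    diag(Q) <- q_r
    Q
}

#' Transition probability between pair states
#'
#' @param N number of haplotype paths.
#' @param d recombination distance.
#' @param from,to integer pairs `c(k, l)` and `c(i, j)` of haplotype indices.
#' @export
pair_transition_prob <- function(N, d, from, to) {
    Q <- ls_transition_matrix(N, d)
    Q[from[1], to[1]] * Q[from[2], to[2]]
}

#' Forward-backward posteriors over pair states
#'
#' Runs the scaled forward-backward recursion over one chain of bubbles.
#' The start distribution over the N^2 states of the first bubble is
#' uniform. State (i, j) of bubble v is entry `[i, j]` of the returned
#' posterior matrices.
#'
#' @param log_emissions list of N x N matrices of state log-emissions, one
#'   per bubble, in chain order.
#' @param dists reference gaps (bp) between consecutive bubbles (length
#'   one less than the number of bubbles); each is floored at 1 bp.
#' @param N number of haplotype paths.
#' @param r,Ne Li-Stephens parameters (see [recomb_distance()]).
#' @return list with `posteriors` (list of N x N matrices, each summing to
#'   1) and `loglik` (total log-likelihood of the chain).
#' @export
forward_backward <- function(log_emissions, dists, N, r = 0.0126, Ne = 25000) {
    M <- length(log_emissions)
    stopifnot(M >= 1, length(dists) == M - 1)
    shifts <- vapply(log_emissions, max, 0)
    if (any(!is.finite(shifts)))
        stop(sprintf("non-finite emission log-probabilities at bubble %d",
                     which(!is.finite(shifts))[1]))
    E <- lapply(seq_len(M), function(v) exp(log_emissions[[v]] - shifts[v]))
    Qs <- lapply(dists, function(x)
        ls_transition_matrix(N, recomb_distance(max(x, 1), r, Ne)))

    alpha <- vector("list", M)
    cs <- numeric(M)
    a <- E[[1]] / N^2                    # uniform start transitions
    cs[1] <- sum(a)
    alpha[[1]] <- a / cs[1]
    if (M > 1) for (v in 2:M) {
        a <- (t(Qs[[v - 1]]) %*% alpha[[v - 1]] %*% Qs[[v - 1]]) * E[[v]]
        cs[v] <- sum(a)
        if (cs[v] <= 0 || !is.finite(cs[v]))
            stop(sprintf("forward scaling failed at bubble %d", v))
        alpha[[v]] <- a / cs[v]
    }

    beta <- vector("list", M)
    beta[[M]] <- matrix(1, N, N)
    if (M > 1) for (v in (M - 1):1) {
        b <- Qs[[v]] %*% (E[[v + 1]] * beta[[v + 1]]) %*% t(Qs[[v]])
        beta[[v]] <- b / cs[v + 1]
    }

    posteriors <- lapply(seq_len(M), function(v) {
        p <- alpha[[v]] * beta[[v]]
        p / sum(p)
    })
    list(posteriors = posteriors, loglik = sum(log(cs)) + sum(shifts))
}

#' Genotype likelihoods from state posteriors
#'
#' States (i, j) and (j, i) carry the same unordered allele pair, and
#' several paths can carry the same allele; posteriors of all states mapping
#' to the same unordered allele pair are summed. The called genotype is the
#' argmax (ties broken toward the lowest allele pair in VCF genotype order)
#' and the genotype quality is `round(-10 log10(1 - P(called)))`, capped.
#'
#' @param bubble one bubble of a `"pangenome"`.
#' @param posterior N x N posterior matrix for that bubble.
#' @param gq_cap maximum reported genotype quality.
#' @return list with `likelihoods` (named vector over unordered genotypes
#'   "a/b" in VCF order, summing to 1), `genotype` (integer pair), `gq`.
#' @export
genotype_likelihoods <- function(bubble, posterior, gq_cap = 10000L) {
    nA <- length(bubble$alleles)
    pairs <- genotype_pair_order(nA)
    lik <- setNames(numeric(nrow(pairs)),
                    sprintf("%d/%d", pairs[, 1], pairs[, 2]))
    ai <- bubble$paths   # 0-based allele per path
    N <- length(ai)
    al_i <- matrix(ai, N, N)       # allele of i in state (i, j)
    al_j <- matrix(ai, N, N, byrow = TRUE)
    key <- sprintf("%d/%d", pmin(al_i, al_j), pmax(al_i, al_j))
    sums <- tapply(as.vector(posterior), as.vector(key), sum)
    lik[names(sums)] <- sums
    lik <- lik / sum(lik)
    best <- which.max(lik)         # which.max takes the first (lowest) on ties
    p_best <- lik[[best]]
    gq <- if (p_best >= 1) gq_cap else min(gq_cap, round(-10 * log10(1 - p_best)))
    list(likelihoods = lik, genotype = as.integer(pairs[best, ]), gq = as.integer(gq))
}

# Unordered genotype order used by VCF GL fields: (j,k) with j <= k, ordered
# by index k(k+1)/2 + j.
genotype_pair_order <- function(n_alleles) {
    do.call(rbind, lapply(0:(n_alleles - 1L), function(b)
        cbind(0:b, b)))
}
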