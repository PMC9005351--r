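test_that("Li-Stephens transition probabilities reproduce the closed-form values", {
    # N = 2, d = 2 ln 2: exp(-d/N) = 1/2, p_r = 1/4, q_r = 3/4
    Q <- ls_transition_matrix(2, 2 * log(2))
    expect_equal(Q[1, 1], 0.75)
    expect_equal(Q[1, 2], 0.25)
    expect_equal(pair_transition_prob(2, 2 * log(2), c(1, 1), c(2, 2)), 0.0625)
    expect_equal(pair_transition_prob(2, 2 * log(2), c(1, 1), c(1, 1)), 0.5625)
    expect_equal(pair_transition_prob(2, 2 * log(2), c(1, 1), c(1, 2)), 0.1875)
})

test_that("transition matrices are stochastic, collapse to identity at x=0 and to uniform at large x", {
    for (N in c(2, 3, 5, 10)) for (r in c(0.0126, 1.26)) for (Ne in c(100, 25000)) {
        for (x in c(0, 1, 50, 1000, 1e6)) {
            Q <- ls_transition_matrix(N, recomb_distance(x, r, Ne))
            expect_equal(rowSums(Q), rep(1, N), tolerance = 1e-12)
            P <- kronecker(Q, Q)
            expect_equal(rowSums(P), rep(1, N^2), tolerance = 1e-12)
        }
        expect_equal(ls_transition_matrix(N, 0), diag(N))
        Qinf <- ls_transition_matrix(N, 1e12)
        expect_equal(Qinf, matrix(1 / N, N, N), tolerance = 1e-9)
    }
})

test_that("switch probability increases monotonically with distance toward the uniform limit", {
    N <- 4
    d <- recomb_distance(c(1, 10, 100, 1000, 1e4, 1e5), 0.0126, 25000)
    stay <- vapply(d, function(dd) ls_transition_matrix(N, dd)[1, 1], 0)
    expect_true(all(diff(stay) < 0))
    expect_gt(min(stay), 1 / N)
})

test_that("emission log-probabilities follow Poisson / geometric pmfs by copy number", {
    m <- emission_model(20)
    # hand Poisson pmf: c^... log(lambda^c e^-lambda / c!)
    hand_pois <- function(c, lam) c * log(lam) - lam - lgamma(c + 1)
    expect_equal(kmer_count_logpmf(m, 20L, 2L), hand_pois(20, 20))
    expect_equal(kmer_count_logpmf(m, 7L, 1L), hand_pois(7, 10))
    expect_equal(kmer_count_logpmf(m, 0L, 0L), log(m$p_geom))
    expect_equal(kmer_count_logpmf(m, 3L, 0L),
                 log(m$p_geom) + 3 * log(1 - m$p_geom))
    # empty k-mer set emits probability exactly 1
    expect_identical(emission_logprob(m, integer(0), integer(0)), 0)
    expect_error(emission_logprob(m, -1L, 1L), "negative")
    # each copy-number distribution is a proper pmf
    for (cn in 0:2)
        expect_equal(sum(exp(kmer_count_logpmf(m, 0:500, rep(cn, 501)))), 1,
                     tolerance = 1e-9)
})

test_that("emission probability is symmetric in the state's haplotype order", {
    panel <- random_test_panel(71, n_var = 4, N = 4, len = 2000, min_gap = 70)
    pg <- build_bubbles(panel, k = 13)
    tab <- count_graph_kmers(pg)
    ksets <- select_unique_kmers(pg, tab)
    m <- emission_model(15)
    set.seed(1)
    for (b in seq_along(pg$bubbles)) {
        ks <- ksets[[b]]
        if (!length(ks$kmers)) next
        counts <- rpois(length(ks$kmers), 8)
        for (i in 1:4) for (j in 1:4) {
            e_ij <- emission_logprob(m, counts, copy_number_vector(pg$bubbles[[b]], ks, i, j))
            e_ji <- emission_logprob(m, counts, copy_number_vector(pg$bubbles[[b]], ks, j, i))
            expect_equal(e_ij, e_ji)
        }
    }
})

test_that("forward-backward posteriors match exhaustive path-pair enumeration", {
    set.seed(123)
    for (rep in 1:20) {
        N <- sample(2:4, 1)
        M <- sample(2:4, 1)
        if (N^(2 * M) > 20000) M <- 2
        logE <- lapply(seq_len(M), function(v) {
            E <- matrix(rnorm(N * N, sd = 3), N, N)
            (E + t(E)) / 2
        })
        dists <- sample(c(1, 50, 500, 5000), M - 1, replace = TRUE)
        fb <- forward_backward(logE, dists, N, r = 0.0126, Ne = 25000)
        bf <- bf_forward_backward(logE, dists, N, r = 0.0126, Ne = 25000)
        expect_equal(fb$loglik, bf$loglik, tolerance = 1e-10)
        for (v in seq_len(M)) {
            expect_equal(sum(fb$posteriors[[v]]), 1, tolerance = 1e-8)
            expect_equal(fb$posteriors[[v]], bf$posteriors[[v]],
                         tolerance = 1e-10)
        }
    }
})

test_that("an uninformative single bubble yields the uniform posterior and GQ 0", {
    N <- 3
    fb <- forward_backward(list(matrix(0, N, N)), integer(0), N)
    expect_equal(fb$posteriors[[1]], matrix(1 / N^2, N, N))
    bubble <- list(alleles = c("A", "T"), paths = c(0L, 1L, 1L),
                   tuples = rbind(0L, 1L), is_complex = FALSE)
    gl <- genotype_likelihoods(bubble, fb$posteriors[[1]])
    expect_equal(sum(gl$likelihoods), 1)
    # winning mass 4/9: GQ = round(-10 log10(5/9)) = 3
    expect_equal(gl$gq, 3L)
    # uniform over 9 states with alleles (0,1,1): P(0/0)=1/9, P(0/1)=4/9, P(1/1)=4/9
    expect_equal(unname(gl$likelihoods), c(1, 4, 4) / 9)
    expect_equal(gl$genotype, c(0L, 1L))   # argmax tie broken to lowest pair
})

test_that("state posteriors pool into genotype likelihoods over unordered allele pairs", {
    # 3 haplotypes with alleles (0, 0, 1): genotype 0/0 pools the 4 states
    # over haplotype pairs {1,2} x {1,2}
    bubble <- list(alleles = c("A", "G"), paths = c(0L, 0L, 1L),
                   tuples = rbind(0L, 1L), is_complex = FALSE)
    set.seed(5)
    p <- matrix(runif(9), 3, 3)
    p <- p / sum(p)
    gl <- genotype_likelihoods(bubble, p)
    expect_equal(unname(gl$likelihoods["0/0"]), sum(p[1:2, 1:2]))
    expect_equal(unname(gl$likelihoods["0/1"]), sum(p[1:2, 3]) + sum(p[3, 1:2]))
    expect_equal(unname(gl$likelihoods["1/1"]), p[3, 3])
    expect_equal(sum(gl$likelihoods), 1)

    # states (i,j) and (j,i) always pool to the same genotype
    bubble2 <- list(alleles = c("A", "G"), paths = c(0L, 1L),
                    tuples = rbind(0L, 1L), is_complex = FALSE)
    p2 <- matrix(c(0.1, 0.4, 0.3, 0.2), 2, 2)
    gl2 <- genotype_likelihoods(bubble2, p2)
    expect_equal(unname(gl2$likelihoods["0/1"]), 0.4 + 0.3)
})

test_that("genotype quality is the phred-scaled complement of the winning likelihood, capped", {
    bubble <- list(alleles = c("A", "G"), paths = c(0L, 1L),
                   tuples = rbind(0L, 1L), is_complex = FALSE)
    p <- matrix(c(0.9, 0.05, 0.04, 0.01), 2, 2)   # P(0/0) = 0.9
    gl <- genotype_likelihoods(bubble, p)
    expect_equal(gl$gq, as.integer(round(-10 * log10(1 - 0.9))))
    p_certain <- matrix(c(1, 0, 0, 0), 2, 2)
    expect_equal(genotype_likelihoods(bubble, p_certain)$gq, 10000L)
    expect_equal(genotype_likelihoods(bubble, p_certain, gq_cap = 99L)$gq, 99L)
})

test_that("the genotyping fit is deterministic and its methods report the fitted parameters", {
    cfg <- sim_config(seed = 17, ref_length = 20000, n_haplotypes = 6,
                      coverage = 20)
    sim <- simulate_dataset(cfg)
    pg <- build_bubbles(sim$panel, k = 31)
    fit1 <- genotype_sample(pg, sim$reads$reads)
    fit2 <- genotype_sample(pg, sim$reads$reads)
    expect_identical(fit1$calls, fit2$calls)
    expect_identical(fit1$likelihoods, fit2$likelihoods)
    expect_s3_class(fit1, "genotype_fit")
    co <- coef(fit1)
    expect_named(co, c("lambda", "p_geom", "r", "Ne"))
    expect_output(print(fit1), "lambda")
    s <- summary(fit1)
    expect_output(print(s), "per bubble class")
    expect_true(all(vapply(fit1$likelihoods, function(l)
        abs(sum(l) - 1) < 1e-6, TRUE)))
})

test_that("genotyping aborts when coverage cannot be estimated from empty reads", {
    panel <- random_test_panel(81, n_var = 4, N = 4, len = 2000, min_gap = 70)
    pg <- build_bubbles(panel, k = 31)
    expect_error(genotype_sample(pg, character(0)), "coverage")
    # with lambda supplied the fit still runs: zero counts are themselves
    # evidence (they favor the allele pair whose k-mers were not expected),
    # and every bubble gets a normalized likelihood vector
    fit <- genotype_sample(pg, character(0), lambda = 15)
    expect_equal(nrow(fit$calls), length(pg$bubbles))
    expect_true(all(vapply(fit$likelihoods, function(l)
        abs(sum(l) - 1) < 1e-6, TRUE)))
})
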