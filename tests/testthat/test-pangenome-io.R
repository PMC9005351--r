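test_that("a phased multisample VCF parses into one variant per record with stable haplotype order", {
    dir <- withr::local_tempdir()
    fx <- write_tiny_vcf_fixture(dir)
    panel <- read_panel(fx$vcf, fx$fasta)
    expect_s3_class(panel, "panel")
    expect_equal(nrow(panel$variants), 3L)
    expect_equal(panel$haplotype_names, c("SA.1", "SA.2", "SB.1", "SB.2"))
    # record 1: SA 0|1, SB 0|0
    i <- which(panel$variants$pos == 41)
    expect_equal(unname(panel$haps[i, ]), c(0L, 1L, 0L, 0L))
    i <- which(panel$variants$pos == 201)
    expect_equal(panel$variants$type[i], "insertion")
    expect_equal(panel$variants$size[i], 4L)
})

test_that("missing or unphased panel genotypes abort with the position, or drop under the lenient mode", {
    dir <- withr::local_tempdir()
    fx <- write_tiny_vcf_fixture(dir, gts = c("0|1", "0/1", "0|0"))
    expect_error(read_panel(fx$vcf, fx$fasta), "121")
    panel <- read_panel(fx$vcf, fx$fasta, unphased = "drop")
    expect_equal(nrow(panel$variants), 2L)
    fx2 <- write_tiny_vcf_fixture(dir, gts = c("0|1", ".", "0|0"))
    expect_error(read_panel(fx2$vcf, fx2$fasta), "chr1:121")
})

test_that("a REF allele disagreeing with the FASTA aborts with the position", {
    dir <- withr::local_tempdir()
    fx <- write_tiny_vcf_fixture(dir)
    ref2 <- c(chr1 = chartr("AC", "CA", fx$ref))
    expect_error(read_panel(fx$vcf, ref2), "chr1:41")
})

test_that("variant size classes follow the small/midsize/large convention without the anchor base", {
    cls <- classify_variant(c("A", "A", "A", "ACCA"),
                            c("G", paste0("A", strrep("T", 19)),
                              paste0("A", strrep("T", 50)), "A"))
    expect_equal(cls$type, c("SNP", "insertion", "insertion", "deletion"))
    expect_equal(cls$size, c(1L, 19L, 50L, 3L))
    expect_equal(cls$size_class, c("small", "small", "large", "small"))
})

test_that("variants closer than k reference bases merge into one bubble, distant ones stay apart", {
    ref <- c(chrT = rand_seq_fixed(2500, seed = 1))
    mk <- function(positions) {
        vars <- data.frame(chrom = "chrT", pos = positions,
                           ref = substring(ref[[1]], positions, positions),
                           alt = vapply(positions, function(p)
                               setdiff(c("A", "C", "G", "T"),
                                       substr(ref, p, p))[1], ""))
        haps <- rbind(c(0L, 1L, 0L, 1L), c(0L, 0L, 1L, 1L),
                      c(1L, 0L, 0L, 0L))[seq_along(positions), , drop = FALSE]
        make_panel(ref, vars, haps)
    }
    pg <- build_bubbles(mk(c(100, 110)), k = 31)       # 9 bp gap < k
    expect_equal(length(pg$bubbles), 1L)
    # alleles are the distinct two-SNP haplotype sequences over the span
    hapseqs <- vapply(1:4, function(h)
        substr(naive_hap_seq(ref[[1]], mk(c(100, 110))$variants,
                             mk(c(100, 110))$haps[, h]), 100, 110), "")
    expect_setequal(pg$bubbles[[1]]$alleles[pg$bubbles[[1]]$paths + 1L], hapseqs)
    expect_true(pg$bubbles[[1]]$is_complex)

    pg2 <- build_bubbles(mk(c(100, 1100)), k = 31)     # 999 bp gap
    expect_equal(length(pg2$bubbles), 2L)
    expect_false(any(pg2$info$complex))

    # gap of exactly k stays separate (strict inequality)
    pg3 <- build_bubbles(mk(c(100, 132)), k = 31)
    expect_equal(length(pg3$bubbles), 2L)
    pg4 <- build_bubbles(mk(c(100, 131)), k = 31)
    expect_equal(length(pg4$bubbles), 1L)

    # transitive chain merging
    pg5 <- build_bubbles(mk(c(100, 110, 120)), k = 31)
    expect_equal(length(pg5$bubbles), 1L)
    expect_equal(nrow(pg5$bubbles[[1]]$src), 3L)
})

test_that("bubble membership matches the single-linkage interval clustering oracle on random panels", {
    for (seed in 1:5) {
        panel <- random_test_panel(seed, n_var = 10, N = 4, len = 3000,
                                   min_gap = 10)
        pg <- build_bubbles(panel, k = 31)
        starts <- panel$variants$pos
        ends <- panel$variants$pos + nchar(panel$variants$ref) - 1L
        cl <- oracle_clusters(starts, ends, 31L)
        expect_equal(length(pg$bubbles), max(cl))
        sizes_oracle <- sort(as.integer(table(cl)))
        sizes_pkg <- sort(vapply(pg$bubbles, function(b) nrow(b$src), 0L))
        expect_equal(sizes_pkg, sizes_oracle)
        # bubbles are ordered and non-overlapping after merging
        expect_true(all(diff(pg$info$start) > 0))
        expect_true(all(pg$info$start[-1] > pg$info$end[-nrow(pg$info)]))
    }
})

test_that("bubble alleles enumerate the distinct haplotype substrings over the merged span", {
    for (seed in 6:9) {
        panel <- random_test_panel(seed, n_var = 8, N = 6, len = 3000,
                                   min_gap = 15)
        pg <- build_bubbles(panel, k = 31)
        hap_seqs <- vapply(seq_len(6), function(h)
            naive_hap_seq(panel$reference[[1]], panel$variants,
                          panel$haps[, h]), "")
        pkg_paths <- haplotype_path_seqs(pg)$chrT
        expect_equal(pkg_paths, hap_seqs)
        for (b in seq_along(pg$bubbles)) {
            bb <- pg$bubbles[[b]]
            expect_equal(bb$alleles[1],
                         substr(panel$reference[[1]], bb$start, bb$end))
            used <- sort(unique(bb$paths))
            expect_true(all(bb$paths >= 0 & bb$paths < length(bb$alleles)))
            # every non-reference allele is used by at least one haplotype
            expect_true(all(seq_along(bb$alleles)[-1] - 1L %in% c(used, 0L) |
                            length(bb$alleles) == 1L))
        }
    }
})

test_that("bubble genotypes decompose to source-variant genotypes and back, exhaustively", {
    ref <- c(chrT = rand_seq_fixed(600, seed = 3))
    p1 <- 200; p2 <- 210
    rb1 <- substr(ref, p1, p1); rb2 <- substr(ref, p2, p2)
    vars <- data.frame(chrom = "chrT", pos = c(p1, p2),
                       ref = c(rb1, rb2),
                       alt = c(setdiff(c("A", "C", "G", "T"), rb1)[1],
                               paste0(rb2, "TTGA")))
    # hap1 ref/ref, hap2 SNP only, hap3+4 SNP+insertion: 3 distinct alleles
    haps <- cbind(c(0L, 0L), c(1L, 0L), c(1L, 1L), c(1L, 1L))
    pg <- build_bubbles(make_panel(ref, vars, haps), k = 31)
    expect_equal(length(pg$bubbles), 1L)
    bb <- pg$bubbles[[1]]
    expect_equal(length(bb$alleles), 3L)
    a_both <- bb$paths[3]           # allele carrying both alts
    expect_equal(unname(bb$tuples[a_both + 1L, ]), c(1L, 1L))
    dec <- decompose_genotypes(bb, c(0L, a_both))
    expect_equal(dec$a1, c(0L, 0L))
    expect_equal(dec$a2, c(1L, 1L))
    dec2 <- decompose_genotypes(bb, c(a_both, a_both))
    expect_equal(dec2$a1, c(1L, 1L))
    expect_equal(dec2$a2, c(1L, 1L))

    # exhaustive: every unordered allele pair decomposes to the allele pair
    # given by the source bookkeeping
    nA <- length(bb$alleles)
    for (a in 0:(nA - 1)) for (b in a:(nA - 1)) {
        d <- decompose_genotypes(bb, c(a, b))
        for (s in seq_len(nrow(bb$src))) {
            pair <- sort(c(bb$tuples[a + 1L, s], bb$tuples[b + 1L, s]))
            expect_equal(c(d$a1[s], d$a2[s]), pair)
        }
    }
})

test_that("a genotyped VCF round-trips: genotypes exactly, likelihoods within 1e-6", {
    panel <- random_test_panel(21, n_var = 6, N = 4, len = 3500, min_gap = 80)
    pg <- build_bubbles(panel, k = 31)
    sim <- list(haplotypes = vapply(c(1, 3), function(h)
        naive_hap_seq(panel$reference[[1]], panel$variants, panel$haps[, h]), ""))
    cfg <- sim_config(seed = 2, coverage = 25, error_rate = 0)
    reads <- simulate_reads(sim$haplotypes, cfg)$reads
    fit <- genotype_sample(pg, reads)
    dir <- withr::local_tempdir()

    vb <- file.path(dir, "bubble.vcf")
    write_genotyped_vcf(fit, vb, mode = "bubble")
    back <- read_genotyped_vcf(vb)
    expect_equal(nrow(back), length(pg$bubbles))
    expect_equal(back$gt, fit$calls$gt)
    expect_equal(back$gq, as.numeric(fit$calls$gq))
    for (b in seq_len(nrow(back)))
        expect_equal(back$gl[[b]],
                     log10(pmax(unname(fit$likelihoods[[b]]), 1e-300)),
                     tolerance = 1e-6)

    vd <- file.path(dir, "decomposed.vcf")
    write_genotyped_vcf(fit, vd, mode = "decomposed")
    dback <- read_genotyped_vcf(vd)
    expect_setequal(dback$id, panel$variants$src_id)
    dec <- decompose_calls(fit)
    m <- match(dback$id, dec$src_id)
    expect_equal(dback$gt, sprintf("%d/%d", dec$a1[m], dec$a2[m]))
})

test_that("re-parsing a written panel VCF reproduces the same pangenome", {
    panel <- random_test_panel(31, n_var = 8, N = 6, len = 4000, min_gap = 20)
    dir <- withr::local_tempdir()
    vcf <- file.path(dir, "panel.vcf")
    write_panel_vcf(panel, vcf)
    panel2 <- read_panel(vcf, panel$reference)
    expect_equal(panel2$variants$src_id, panel$variants$src_id)
    expect_equal(unname(panel2$haps), unname(panel$haps))
    pg <- build_bubbles(panel, k = 31)
    pg2 <- build_bubbles(panel2, k = 31)
    expect_equal(pg2$info, pg$info)
    for (b in seq_along(pg$bubbles)) {
        expect_equal(pg2$bubbles[[b]]$alleles, pg$bubbles[[b]]$alleles)
        expect_equal(pg2$bubbles[[b]]$paths, pg$bubbles[[b]]$paths)
    }
})
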