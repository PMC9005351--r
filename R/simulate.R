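# Synthetic data generator: reference with planted tandem-repeat arrays, a
# phased haplotype panel carrying SNPs/indels/SVs (including repeat-embedded
# copy-number indels and overlapping-variant clusters that force complex
# bubbles), a diploid sample drawn as a recombinant mosaic of the panel
# paths, and substitution-error short reads. Everything is reproducible
# bit-for-bit under the config seed: each stage derives its own seed
# (seed, seed+1, seed+2, seed+3) so stages can also be rerun in isolation.

#' Simulation configuration
#'
#' Defaults describe the standard desk-scale study conditions: a 150 kb
#' chromosome at 41% GC with 12% of its length in planted tandem-repeat
#' arrays; 10 panel haplotypes with per-bp variant rates 3e-3 (SNP), 6e-4
#' (indel 1-49 bp) and 8e-5 (SV 50-300 bp); a quarter of variants placed
#' inside repeat arrays (repeat-embedded indels/SVs change whole repeat-unit
#' copy numbers, so they typically lack unique k-mers); 8% of variants get
#' an overlapping partner on other haplotypes (forcing complex bubbles);
#' sample haplotypes switch panel paths at 1e-5 per bp; 100 bp reads at
#' 30x coverage with 0.1% substitution error.
#'
#' @param seed integer seed making every output reproducible.
#' @param ref_length,gc reference length (bp) and GC content.
#' @param repeat_fraction fraction of the reference covered by planted
#'   tandem-repeat arrays.
#' @param repeat_unit_range repeat unit length range (bp).
#' @param n_haplotypes number of panel haplotypes (even).
#' @param snp_rate,indel_rate,sv_rate per-bp variant rates.
#' @param frac_in_repeat fraction of variants placed inside repeat arrays.
#' @param cluster_rate fraction of variants receiving an overlapping partner
#'   variant (on disjoint haplotypes), which produces multiallelic bubbles.
#' @param sample_switch_rate per-bp recombination rate of the sample mosaic.
#' @param read_length,coverage,error_rate read simulation parameters.
#' @export
sim_config <- function(seed = 1L, ref_length = 150000L, gc = 0.41,
                       repeat_fraction = 0.12, repeat_unit_range = c(2L, 100L),
                       n_haplotypes = 10L,
                       snp_rate = 3e-3, indel_rate = 6e-4, sv_rate = 8e-5,
                       frac_in_repeat = 0.25, cluster_rate = 0.08,
                       sample_switch_rate = 1e-5,
                       read_length = 100L, coverage = 30, error_rate = 0.001) {
    cfg <- list(seed = as.integer(seed), ref_length = as.integer(ref_length),
                gc = gc, repeat_fraction = repeat_fraction,
                repeat_unit_range = as.integer(repeat_unit_range),
                n_haplotypes = as.integer(n_haplotypes),
                snp_rate = snp_rate, indel_rate = indel_rate, sv_rate = sv_rate,
                frac_in_repeat = frac_in_repeat, cluster_rate = cluster_rate,
                sample_switch_rate = sample_switch_rate,
                read_length = as.integer(read_length), coverage = coverage,
                error_rate = error_rate)
    stopifnot(cfg$ref_length > 1000, cfg$gc > 0, cfg$gc < 1,
              cfg$repeat_fraction >= 0, cfg$repeat_fraction < 1,
              cfg$n_haplotypes >= 2, cfg$n_haplotypes %% 2L == 0L,
              cfg$snp_rate >= 0, cfg$indel_rate >= 0, cfg$sv_rate >= 0,
              cfg$frac_in_repeat >= 0, cfg$frac_in_repeat <= 1,
              cfg$cluster_rate >= 0, cfg$sample_switch_rate >= 0,
              cfg$coverage > 0, cfg$error_rate >= 0, cfg$error_rate < 1)
    structure(cfg, class = "sim_config")
}

random_seq <- function(n, gc) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
}

revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate a reference chromosome with planted tandem repeats
#'
#' @param config a [sim_config()].
#' @return list with `seqs` (named character vector, one chromosome) and
#'   `repeats` (data frame of planted arrays: chrom, start, end, unit).
#' @export
simulate_reference <- function(config) {
    set.seed(config$seed)
    L <- config$ref_length
    base <- strsplit(random_seq(L, config$gc), "")[[1]]
    target <- config$repeat_fraction * L
    placed <- 0
    arrays <- list()
    occupied <- logical(L)
    tries <- 0L
    while (placed < target && tries < 10000L) {
        tries <- tries + 1L
        u <- sample(config$repeat_unit_range[1]:config$repeat_unit_range[2], 1L)
        alen <- sample(60:600, 1L)
        copies <- max(2L, ceiling(alen / u))
        alen <- copies * u
        s <- sample.int(L - alen - 1000L, 1L) + 500L
        if (any(occupied[max(1, s - 200L):min(L, s + alen + 199L)])) next
        unit <- random_seq(u, config$gc)
        base[s:(s + alen - 1L)] <- strsplit(strrep(unit, copies), "")[[1]]
        occupied[s:(s + alen - 1L)] <- TRUE
        arrays[[length(arrays) + 1L]] <-
            data.frame(chrom = "chr1", start = s, end = s + alen - 1L,
                       unit = unit, stringsAsFactors = FALSE)
        placed <- placed + alen
    }
    reps <- if (length(arrays)) do.call(rbind, arrays)
            else data.frame(chrom = character(0), start = integer(0),
                            end = integer(0), unit = character(0))
    list(seqs = c(chr1 = paste(base, collapse = "")), repeats = reps)
}

#' Simulate a phased haplotype panel
#'
#' Variants are placed at the configured per-bp rates; a configured fraction
#' sits inside the planted repeat arrays (indels and SVs there change the
#' copy number of whole repeat units, emulating VNTR/STR variation with no
#' unique k-mers); a configured fraction of variants receives an overlapping
#' partner carried by disjoint haplotypes, which forces a multiallelic
#' bubble. Carrier haplotypes are drawn uniformly (1 to N-1 carriers);
#' overlapping non-reference alleles never co-occur on one haplotype.
#'
#' @param reference output of [simulate_reference()].
#' @param config a [sim_config()].
#' @return a `"panel"` object (as from [read_panel()]) whose `variants`
#'   data frame additionally carries an `in_repeat` flag.
#' @export
simulate_panel <- function(reference, config) {
    set.seed(config$seed + 1L)
    seqs <- reference$seqs
    N <- config$n_haplotypes
    chrom <- names(seqs)[1]
    seq_chrom <- seqs[[chrom]]
    L <- nchar(seq_chrom)
    margin <- 300L
    occ <- matrix(FALSE, nrow = L, ncol = N)   # per-haplotype occupied bases
    reps <- reference$repeats[reference$repeats$chrom == chrom, , drop = FALSE]

    vars <- list()
    used_keys <- character(0)
    add_variant <- function(pos, ref, alt, carriers, in_repeat) {
        key <- sprintf("%d:%s>%s", pos, ref, alt)
        if (key %in% used_keys) return(FALSE)   # variant keys must be unique
        s <- pos; e <- pos + nchar(ref) - 1L
        if (any(occ[s:e, carriers])) return(FALSE)
        used_keys <<- c(used_keys, key)
        occ[s:e, carriers] <<- TRUE
        al <- integer(N); al[carriers] <- 1L
        vars[[length(vars) + 1L]] <<- list(
            chrom = chrom, pos = pos, ref = ref, alt = alt,
            haps = al, in_repeat = in_repeat)
        TRUE
    }
    draw_carriers <- function(pos, end) {
        free <- which(!apply(occ[pos:end, , drop = FALSE], 2, any))
        if (length(free) < 1L) return(integer(0))
        m <- sample.int(max(1L, min(N - 1L, length(free))), 1L)
        sample(free, m)
    }
    base_at <- function(p) substr(seq_chrom, p, p)
    other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)

    n_snp <- round(L * config$snp_rate)
    n_indel <- round(L * config$indel_rate)
    n_sv <- round(L * config$sv_rate)

    place_repeat_indel <- function(size_lo, size_hi) {
        # copy-number change of whole repeat units inside a planted array
        cand <- which(reps$end - reps$start + 1L >= 2L * size_lo)
        if (!length(cand)) return(FALSE)
        a <- reps[sample(cand, 1L), ]
        u <- nchar(a$unit)
        n_units <- max(1L, round(runif(1, size_lo, size_hi) / u))
        sz <- n_units * u
        if (sz > (a$end - a$start + 1L) - u) return(FALSE)
        anchor <- a$start - 1L + u * sample.int((a$end - a$start + 1L - sz) %/% u, 1L)
        del <- runif(1) < 0.5
        if (del) { ref <- substr(seq_chrom, anchor, anchor + sz); alt <- base_at(anchor) }
        else { ref <- base_at(anchor); alt <- paste0(ref, substr(seq_chrom, anchor + 1L, anchor + sz)) }
        carriers <- draw_carriers(anchor, anchor + nchar(ref) - 1L)
        if (!length(carriers)) return(FALSE)
        add_variant(anchor, ref, alt, carriers, TRUE)
    }
    place_plain_indel <- function(size_lo, size_hi) {
        sz <- sample(size_lo:size_hi, 1L)
        pos <- sample.int(L - margin - sz, 1L) + margin %/% 2L
        del <- runif(1) < 0.5
        if (del) { ref <- substr(seq_chrom, pos, pos + sz); alt <- base_at(pos) }
        else { ref <- base_at(pos); alt <- paste0(ref, random_seq(sz, config$gc)) }
        carriers <- draw_carriers(pos, pos + nchar(ref) - 1L)
        if (!length(carriers)) return(FALSE)
        in_rep <- any(reps$start <= pos + nchar(ref) - 1L & reps$end >= pos)
        add_variant(pos, ref, alt, carriers, in_rep)
    }
    place_snp <- function(in_repeat) {
        if (in_repeat && nrow(reps)) {
            a <- reps[sample.int(nrow(reps), 1L), ]
            pos <- sample(a$start:a$end, 1L)
        } else {
            pos <- sample.int(L - margin, 1L) + margin %/% 2L
        }
        rb <- base_at(pos)
        carriers <- draw_carriers(pos, pos)
        if (!length(carriers)) return(FALSE)
        in_rep <- any(reps$start <= pos & reps$end >= pos)
        add_variant(pos, rb, other_base(rb), carriers, in_rep)
    }

    n_try <- function(n, f, ...) {
        done <- 0L; tries <- 0L
        while (done < n && tries < 50L * n + 100L) {
            tries <- tries + 1L
            if (isTRUE(f(...))) done <- done + 1L
        }
        done
    }
    n_sv_rep <- round(n_sv * config$frac_in_repeat)
    n_try(n_sv_rep, place_repeat_indel, 50L, 300L)
    n_try(n_sv - n_sv_rep, place_plain_indel, 50L, 300L)
    n_indel_rep <- round(n_indel * config$frac_in_repeat)
    n_try(n_indel_rep, place_repeat_indel, 2L, 49L)
    n_try(n_indel - n_indel_rep, place_plain_indel, 1L, 49L)
    n_snp_rep <- round(n_snp * config$frac_in_repeat)
    n_try(n_snp_rep, place_snp, TRUE)
    n_try(n_snp - n_snp_rep, place_snp, FALSE)

    # overlapping-variant clusters: add a partner variant on disjoint haplotypes
    n_cluster <- round(length(vars) * config$cluster_rate)
    if (n_cluster > 0) {
        dels <- which(vapply(vars, function(v) nchar(v$ref) >= 4L, FALSE))
        snps <- which(vapply(vars, function(v)
            nchar(v$ref) == 1L && nchar(v$alt) == 1L, FALSE))
        made <- 0L; tries <- 0L
        while (made < n_cluster && tries < 50L * n_cluster + 100L) {
            tries <- tries + 1L
            if (length(dels) && runif(1) < 0.5) {
                v <- vars[[sample(dels, 1L)]]
                pos <- v$pos + sample.int(nchar(v$ref) - 1L, 1L)
                rb <- base_at(pos)
                carriers <- draw_carriers(pos, pos)
                if (length(carriers) &&
                    add_variant(pos, rb, other_base(rb), carriers, v$in_repeat))
                    made <- made + 1L
            } else if (length(snps)) {
                v <- vars[[sample(snps, 1L)]]
                alt2 <- sample(setdiff(c("A", "C", "G", "T"), c(v$ref, v$alt)), 1L)
                carriers <- draw_carriers(v$pos, v$pos)
                if (length(carriers) &&
                    add_variant(v$pos, v$ref, alt2, carriers, v$in_repeat))
                    made <- made + 1L
            } else break
        }
    }
    if (!length(vars)) {
        variants <- data.frame(chrom = character(0), pos = integer(0),
                               ref = character(0), alt = character(0),
                               src_id = character(0), type = character(0),
                               size = integer(0), size_class = character(0),
                               in_repeat = logical(0))
        haps <- matrix(0L, 0L, N)
    } else {
        variants <- data.frame(
            chrom = vapply(vars, `[[`, "", "chrom"),
            pos = vapply(vars, `[[`, 0L, "pos"),
            ref = vapply(vars, `[[`, "", "ref"),
            alt = vapply(vars, `[[`, "", "alt"),
            stringsAsFactors = FALSE)
        variants$src_id <- sprintf("%s:%d:%s>%s", variants$chrom, variants$pos,
                                   variants$ref, variants$alt)
        cls <- classify_variant(variants$ref, variants$alt)
        variants$type <- cls$type
        variants$size <- cls$size
        variants$size_class <- cls$size_class
        variants$in_repeat <- vapply(vars, `[[`, FALSE, "in_repeat")
        haps <- do.call(rbind, lapply(vars, `[[`, "haps"))
        o <- order(variants$chrom, variants$pos, variants$alt)
        variants <- variants[o, , drop = FALSE]
        haps <- haps[o, , drop = FALSE]
    }
    sample_names <- sprintf("S%d", seq_len(N %/% 2L))
    structure(list(variants = variants, haps = haps,
                   haplotype_names = as.vector(t(outer(sample_names, 1:2,
                                                       paste, sep = "."))),
                   reference = seqs),
              class = "panel")
}

#' Write a panel as a phased multisample VCF
#'
#' @param panel a `"panel"` object.
#' @param path output VCF path.
#' @export
write_panel_vcf <- function(panel, path) {
    N <- length(panel$haplotype_names)
    samples <- unique(sub("\\.\\d+$", "", panel$haplotype_names))
    hdr <- c("##fileformat=VCFv4.2",
             "##source=panotype-simulator",
             sprintf("##contig=<ID=%s,length=%d>", names(panel$reference),
                     nchar(panel$reference)),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
    rows <- vapply(seq_len(nrow(panel$variants)), function(i) {
        gts <- vapply(seq_len(N %/% 2L), function(s)
            sprintf("%d|%d", panel$haps[i, 2L * s - 1L], panel$haps[i, 2L * s]), "")
        paste(c(panel$variants$chrom[i], panel$variants$pos[i], ".",
                panel$variants$ref[i], panel$variants$alt[i], ".", "PASS", ".",
                "GT", gts), collapse = "\t")
    }, "")
    writeLines(c(hdr, rows), path)
    invisible(path)
}

#' Simulate a diploid sample as a recombinant mosaic of panel haplotypes
#'
#' Each sample haplotype walks along the chromosome copying one panel path,
#' switching to a different path at Poisson(switch rate x length) points.
#' The truth genotype per variant records the alleles actually applied: if a
#' mid-cluster switch selects overlapping non-reference alleles, the later
#' (unspellable) allele is dropped and recorded as reference.
#'
#' @param panel a `"panel"`.
#' @param config a [sim_config()].
#' @return list with `haplotypes` (two sequences), `truth` (variants data
#'   frame with a1/a2 truth alleles), `paths` (per-haplotype data frame of
#'   mosaic segments), `n_switches`.
#' @export
simulate_sample <- function(panel, config) {
    set.seed(config$seed + 2L)
    N <- length(panel$haplotype_names)
    chrom <- names(panel$reference)[1]
    seq_chrom <- panel$reference[[chrom]]
    L <- nchar(seq_chrom)
    vv <- panel$variants
    truth_al <- matrix(0L, nrow(vv), 2L)
    hap_seqs <- character(2L)
    seg_log <- list()
    n_switches <- 0L
    for (h in 1:2) {
        n_sw <- rpois(1L, config$sample_switch_rate * L)
        bp <- sort(sample.int(L - 1L, min(n_sw, L - 2L)))
        starts <- c(1L, bp + 1L)
        path <- integer(length(starts))
        path[1] <- sample.int(N, 1L)
        for (s in seq_along(path)[-1])
            path[s] <- sample(setdiff(seq_len(N), path[s - 1L]), 1L)
        n_switches <- n_switches + length(bp)
        seg_log[[h]] <- data.frame(hap = h, start = starts,
                                   end = c(bp, L), path = path)
        active <- path[findInterval(vv$pos, starts)]
        allele <- panel$haps[cbind(seq_len(nrow(vv)), active)]
        res <- spell_sample_hap(seq_chrom, vv, allele)
        hap_seqs[h] <- res$seq
        truth_al[, h] <- res$applied
    }
    truth <- vv
    truth$a1 <- pmin(truth_al[, 1], truth_al[, 2])
    truth$a2 <- pmax(truth_al[, 1], truth_al[, 2])
    list(haplotypes = hap_seqs, truth = truth,
         paths = do.call(rbind, seg_log), n_switches = n_switches)
}

# Tolerant haplotype speller: overlapping non-reference alleles (possible
# when a mosaic switches inside a variant cluster) drop the later variant,
# recording it as reference.
spell_sample_hap <- function(seq_chrom, vars, allele) {
    o <- order(vars$pos)
    applied <- as.integer(allele)
    cur <- 1L
    parts <- character(0)
    for (i in o) {
        if (allele[i] == 0L) next
        vs <- vars$pos[i]
        if (vs < cur) { applied[i] <- 0L; next }
        if (vs > cur) parts <- c(parts, substr(seq_chrom, cur, vs - 1L))
        parts <- c(parts, vars$alt[i])
        cur <- vs + nchar(vars$ref[i])
    }
    if (cur <= nchar(seq_chrom)) parts <- c(parts, substr(seq_chrom, cur, nchar(seq_chrom)))
    list(seq = paste(parts, collapse = ""), applied = applied)
}

#' Simulate substitution-error short reads from two haplotypes
#'
#' Uniform read starts over each haplotype at coverage/2; iid substitution
#' errors at the configured per-base rate; each read is reverse-complemented
#' with probability 1/2.
#'
#' @param haplotypes character vector of two haplotype sequences.
#' @param config a [sim_config()].
#' @return list with `reads` (character vector) and `log` (data frame of
#'   hap, start, n_errors per read).
#' @export
simulate_reads <- function(haplotypes, config) {
    set.seed(config$seed + 3L)
    rl <- config$read_length
    reads <- character(0)
    logs <- list()
    for (h in seq_along(haplotypes)) {
        len <- nchar(haplotypes[h])
        n <- round(config$coverage / length(haplotypes) * len / rl)
        starts <- sample.int(len - rl + 1L, n, replace = TRUE)
        rd <- substring(haplotypes[h], starts, starts + rl - 1L)
        n_err <- rbinom(n, rl, config$error_rate)
        for (i in which(n_err > 0L)) {
            pos <- sample.int(rl, n_err[i])
            s <- strsplit(rd[i], "")[[1]]
            s[pos] <- vapply(s[pos], function(b)
                sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
            rd[i] <- paste(s, collapse = "")
        }
        flip <- runif(n) < 0.5
        if (any(flip)) rd[flip] <- revcomp(rd[flip])
        reads <- c(reads, rd)
        logs[[h]] <- data.frame(hap = h, start = starts, n_errors = n_err)
    }
    list(reads = reads, log = do.call(rbind, logs))
}

#' Simulate a complete dataset (reference, panel, sample, reads)
#'
#' Runs all four simulation stages; optionally writes reference FASTA, panel
#' VCF, reads FASTQ and a truth TSV into a directory.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory (created if missing).
#' @return list with `reference`, `panel`, `sample`, `reads`, `config`, and
#'   (when written) `files`.
#' @export
simulate_dataset <- function(config = sim_config(), out_dir = NULL) {
    reference <- simulate_reference(config)
    panel <- simulate_panel(reference, config)
    smp <- simulate_sample(panel, config)
    rds <- simulate_reads(smp$haplotypes, config)
    out <- list(reference = reference, panel = panel, sample = smp,
                reads = rds, config = config)
    if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        files <- list(
            reference = file.path(out_dir, "reference.fa"),
            panel = file.path(out_dir, "panel.vcf"),
            reads = file.path(out_dir, "reads.fq"),
            truth = file.path(out_dir, "truth.tsv"),
            repeats = file.path(out_dir, "repeats.bed"))
        write_fasta(reference$seqs, files$reference)
        write_panel_vcf(panel, files$panel)
        write_fastq(rds$reads, files$reads)
        write.table(smp$truth, files$truth, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        write.table(data.frame(reference$repeats$chrom,
                               reference$repeats$start - 1L,
                               reference$repeats$end),
                    files$repeats, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
        out$files <- files
    }
    out
}
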