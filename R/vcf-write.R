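#' Write genotyping results as VCF
#'
#' Emits a VCF 4.2 file with FORMAT `GT:GQ:GL` (GL log10-scaled over
#' unordered genotypes in standard VCF ordering). `mode = "bubble"` writes
#' one (possibly multiallelic) record per bubble; `mode = "decomposed"`
#' converts bubble genotypes back to the original biallelic input variants.
#' The INFO field carries the bubble id (`BUBBLE`), its allele count
#' (`NALL`) and a `COMPLEX` flag for multiallelic bubbles. The header
#' contains no date line, so output is byte-deterministic.
#'
#' @param fit a `"genotype_fit"`.
#' @param path output path.
#' @param mode `"decomposed"` (default) or `"bubble"`.
#' @param sample_name sample column name.
#' @param high_gq optional genotype-quality threshold; calls with GQ below
#'   it are emitted as untyped (`./.`), keeping their GQ and GL.
#' @return the path, invisibly.
#' @export
write_genotyped_vcf <- function(fit, path, mode = c("decomposed", "bubble"),
                                sample_name = "SAMPLE", high_gq = NULL) {
    stopifnot(inherits(fit, "genotype_fit"))
    mode <- match.arg(mode)
    pg <- fit$pangenome
    hdr <- c(
        "##fileformat=VCFv4.2",
        "##source=panotype",
        sprintf("##contig=<ID=%s,length=%d>", names(pg$reference),
                nchar(pg$reference)),
        "##INFO=<ID=BUBBLE,Number=1,Type=Integer,Description=\"Pangenome bubble id\">",
        "##INFO=<ID=NALL,Number=1,Type=Integer,Description=\"Number of bubble alleles\">",
        "##INFO=<ID=COMPLEX,Number=0,Type=Flag,Description=\"Bubble has more than two alleles\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
        "##FORMAT=<ID=GL,Number=G,Type=Float,Description=\"Log10-scaled genotype likelihoods\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                "FORMAT", sample_name), collapse = "\t")
    )
    fmt_gl <- function(gl) paste(sprintf("%.4f", log10(pmax(gl, 1e-300))),
                                 collapse = ",")
    rows <- character(0)
    if (mode == "bubble") {
        for (b in seq_along(pg$bubbles)) {
            bb <- pg$bubbles[[b]]
            gt <- fit$calls$gt[b]
            gq <- fit$calls$gq[b]
            if (!is.null(high_gq) && gq < high_gq) gt <- "./."
            info <- sprintf("BUBBLE=%d;NALL=%d%s", b, length(bb$alleles),
                            if (bb$is_complex) ";COMPLEX" else "")
            rows <- c(rows, paste(
                bb$chrom, bb$start, sprintf("bubble%d", b), bb$alleles[1],
                paste(bb$alleles[-1], collapse = ","), ".", "PASS", info,
                "GT:GQ:GL",
                sprintf("%s:%d:%s", gt, gq, fmt_gl(fit$likelihoods[[b]])),
                sep = "\t"))
        }
    } else {
        dec <- decompose_calls(fit)
        dec <- dec[order(dec$chrom, dec$pos, dec$alt), , drop = FALSE]
        for (i in seq_len(nrow(dec))) {
            b <- dec$bubble[i]
            gt <- sprintf("%d/%d", dec$a1[i], dec$a2[i])
            gq <- dec$gq[i]
            if (!is.null(high_gq) && gq < high_gq) gt <- "./."
            info <- sprintf("BUBBLE=%d;NALL=%d%s", b,
                            length(pg$bubbles[[b]]$alleles),
                            if (pg$bubbles[[b]]$is_complex) ";COMPLEX" else "")
            rows <- c(rows, paste(
                dec$chrom[i], dec$pos[i], dec$src_id[i], dec$ref[i], dec$alt[i],
                ".", "PASS", info, "GT:GQ:GL",
                sprintf("%s:%d:%s", gt, gq, fmt_gl(dec$gl[[i]])),
                sep = "\t"))
        }
    }
    writeLines(c(hdr, rows), path)
    invisible(path)
}

#' Read a genotyped VCF back into a data frame
#'
#' Companion reader for [write_genotyped_vcf()] output (and for any VCF with
#' GT and optionally GQ/GL in FORMAT); used for round-trip checks and by the
#' evaluation tools.
#'
#' @param path VCF path.
#' @return data frame with chrom, pos, id, ref, alt, gt, gq, bubble,
#'   complex, and a `gl` list column (NULL where GL is absent).
#' @export
read_genotyped_vcf <- function(path) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v, getINFO = TRUE)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    getinfo <- function(key) {
        m <- regmatches(fix[, "INFO"],
                        regexpr(paste0("(^|;)", key, "=[^;]*"), fix[, "INFO"]))
        out <- rep(NA_character_, nrow(fix))
        hit <- grepl(paste0("(^|;)", key, "="), fix[, "INFO"])
        out[hit] <- sub(paste0(".*", key, "="), "", m)
        out
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
    gl <- tryCatch(vcfR::extract.gt(v, element = "GL"), error = function(e) NULL)
    one <- function(m) if (is.null(m)) rep(NA_character_, nrow(fix)) else as.character(m[, 1])
    gl_list <- lapply(one(gl), function(s) {
        if (is.na(s)) NULL else as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
    })
    data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
               id = fix[, "ID"], ref = fix[, "REF"], alt = fix[, "ALT"],
               gt = one(gt),
               gq = if (is.null(gq)) NA_real_ else as.numeric(gq[, 1]),
               bubble = as.integer(getinfo("BUBBLE")),
               complex = grepl("(^|;)COMPLEX(;|$)", fix[, "INFO"]),
               gl = I(gl_list),
               stringsAsFactors = FALSE)
}
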