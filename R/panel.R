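#' Read a phased multisample VCF into a haplotype panel
#'
#' Every record must carry a phased genotype (`|` separator) for every sample:
#' the panel defines one complete path per haplotype through the pangenome,
#' so missing or unphased alleles are not representable. Multiallelic records
#' are split into per-ALT biallelic variants before bubble construction so
#' that genotype decomposition is uniform. Haplotype order is
#' `(sample1.1, sample1.2, sample2.1, ...)`, stable across runs.
#'
#' @param vcf_path path to a VCF 4.x file with phased GT for all samples.
#' @param reference reference genome: a named character vector as returned by
#'   [read_reference()], or a FASTA path.
#' @param unphased what to do with a record containing a missing ("." / "./.")
#'   or unphased ("0/1") genotype: `"abort"` (default) stops with the
#'   offending position, `"drop"` removes the record.
#' @return an object of class `"panel"`: a list with `variants` (data frame
#'   with chrom, pos, ref, alt, type, size, size_class, src_id), `haps`
#'   (integer matrix, variants x haplotypes, entries 0/1), `haplotype_names`
#'   and `reference`.
#' @export
read_panel <- function(vcf_path, reference, unphased = c("abort", "drop")) {
    unphased <- match.arg(unphased)
    if (is.character(reference) && length(reference) == 1L && file.exists(reference))
        reference <- read_reference(reference)
    v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    gt <- vcfR::extract.gt(v, element = "GT")
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, colnames(v@gt)[-1]))
    samples <- colnames(gt)
    if (length(samples) < 1L) stop("panel VCF has no sample columns")

    chrom <- fix[, "CHROM"]
    pos <- as.integer(fix[, "POS"])
    ref <- toupper(fix[, "REF"])
    alt <- toupper(fix[, "ALT"])

    ok <- matrix(grepl("^[0-9]+(\\|[0-9]+)+$", gt), nrow = nrow(gt))
    bad <- which(!apply(ok, 1, all))
    if (length(bad)) {
        if (unphased == "abort") {
            stop(sprintf("missing or unphased genotype in panel at %s:%d",
                         chrom[bad[1]], pos[bad[1]]))
        }
        keep <- setdiff(seq_along(pos), bad)
        chrom <- chrom[keep]; pos <- pos[keep]; ref <- ref[keep]; alt <- alt[keep]
        gt <- gt[keep, , drop = FALSE]
    }
    if (length(pos) == 0L) stop("panel VCF contains no usable records")

    if (any(grepl("<", alt, fixed = TRUE)))
        stop("symbolic ALT alleles are unsupported; allele sequences must be explicit")

    ref_obs <- substr(reference[chrom], pos, pos + nchar(ref) - 1L)
    mism <- which(ref_obs != ref)
    if (length(mism))
        stop(sprintf("REF allele disagrees with reference FASTA at %s:%d (VCF %s, FASTA %s)",
                     chrom[mism[1]], pos[mism[1]], ref[mism[1]], ref_obs[mism[1]]))

    # haplotype allele matrix (records x 2*n_samples), allele indices per record
    hap_idx <- do.call(cbind, lapply(samples, function(s) {
        parts <- strsplit(gt[, s], "|", fixed = TRUE)
        n_al <- lengths(parts)
        if (any(n_al != 2L)) stop("panel samples must be diploid (two alleles per genotype)")
        matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE)
    }))
    haplotype_names <- as.vector(t(outer(samples, 1:2, paste, sep = ".")))

    # split multiallelic records to per-ALT biallelic variants
    alt_list <- strsplit(alt, ",", fixed = TRUE)
    rec <- rep(seq_along(pos), lengths(alt_list))
    alt_i <- unlist(lapply(lengths(alt_list), seq_len))
    max_allele <- apply(hap_idx, 1, max)
    if (any(max_allele > lengths(alt_list)))
        stop("genotype allele index exceeds number of ALT alleles")

    variants <- data.frame(
        chrom = chrom[rec],
        pos = pos[rec],
        ref = ref[rec],
        alt = unlist(alt_list),
        src_id = sprintf("%s:%d:%s>%s", chrom[rec], pos[rec], ref[rec],
                         unlist(alt_list)),
        stringsAsFactors = FALSE
    )
    haps <- (hap_idx[rec, , drop = FALSE] == alt_i) * 1L
    cls <- classify_variant(variants$ref, variants$alt)
    variants$type <- cls$type
    variants$size <- cls$size
    variants$size_class <- cls$size_class

    o <- order(variants$chrom, variants$pos, variants$alt)
    structure(list(variants = variants[o, , drop = FALSE],
                   haps = haps[o, , drop = FALSE],
                   haplotype_names = haplotype_names,
                   reference = reference),
              class = "panel")
}

#' Classify variants by type and size
#'
#' Types follow VCF conventions: SNP (both alleles 1 bp), insertion
#' (REF is a prefix anchor of ALT), deletion (ALT is a prefix anchor of REF),
#' otherwise `other`. Indel size is `max(len(ref), len(alt)) - 1`, i.e. the
#' anchor base does not count towards the event length; SNPs have size 1.
#' Size classes: small 1-19 bp, midsize 20-49 bp, large >= 50 bp.
#'
#' @param ref,alt character vectors of REF and ALT allele sequences.
#' @return list with `type`, `size`, `size_class` vectors.
#' @export
classify_variant <- function(ref, alt) {
    nr <- nchar(ref); na <- nchar(alt)
    type <- ifelse(nr == 1L & na == 1L, "SNP",
            ifelse(nr == 1L & na > 1L, "insertion",
            ifelse(na == 1L & nr > 1L, "deletion", "other")))
    size <- ifelse(type == "SNP", 1L, pmax(nr, na) - 1L)
    size_class <- cut(size, breaks = c(0, 19, 49, Inf),
                      labels = c("small", "midsize", "large"))
    list(type = type, size = size, size_class = as.character(size_class))
}

#' @export
print.panel <- function(x, ...) {
    cat(sprintf("Haplotype panel: %d biallelic variant records, %d haplotypes (%d samples)\n",
                nrow(x$variants), length(x$haplotype_names),
                length(x$haplotype_names) / 2L))
    tb <- table(x$variants$type)
    cat("  types:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
    invisible(x)
}
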