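#' @include utils.R
NULL

#' Reference-gene normalization of a peak concentration
#'
#' @param concentration ng/ul from the electropherogram peak.
#' @param referenceFactor reference-gene (e.g. GAPDH) factor for the same
#'   sample, > 0.
#' @param digits decimal places for reporting; \code{NULL} for the
#'   unrounded value.
#' @return normalized concentration (dimensionless).
#' @export
normalizeConcentration <- function(concentration, referenceFactor,
                                   digits = 1) {
    if (any(referenceFactor <= 0)) stop("'referenceFactor' must be positive")
    out <- concentration / referenceFactor
    if (is.null(digits)) out else roundHalfAway(out, digits)
}

#' Expression balance of a consensus tag against its splice variant
#'
#' @param assetNormalized,variantNormalized normalized concentrations of
#'   the two species in one sample.
#' @param digits decimal places for reporting; \code{NULL} for unrounded.
#' @return the ratio, or \code{NA} (variant undetected) when the variant
#'   value is zero.
#' @export
balanceRatio <- function(assetNormalized, variantNormalized, digits = 1) {
    if (variantNormalized == 0) return(NA_real_)
    out <- assetNormalized / variantNormalized
    if (is.null(digits)) out else roundHalfAway(out, digits)
}

#' Signed fold change between two samples
#'
#' r = value(C5.2-like sample) / value(Hb4a-like sample), reported as r
#' when r >= 1 and -1/r otherwise, so a two-fold drop reads -2 rather than
#' 0.5.
#'
#' @param valueCase numerator-sample value (> 0).
#' @param valueControl denominator-sample value (> 0).
#' @param digits decimal places (half-away-from-zero); \code{NULL} for
#'   unrounded.
#' @return signed fold.
#' @examples
#' signedFold(20.0, 95.7)  # -4.8
#' signedFold(98.4, 83.1)  #  1.2
#' @export
signedFold <- function(valueCase, valueControl, digits = 1) {
    if (valueCase <= 0 || valueControl <= 0)
        stop("signed fold requires positive values")
    r <- valueCase / valueControl
    out <- if (r >= 1) r else -1 / r
    if (is.null(digits)) out else roundHalfAway(out, digits)
}

#' Differential call on a signed fold
#'
#' @param fold signed fold change.
#' @param threshold call boundary, default 2 (inclusive: |fold| >= 2).
#' @return logical flag.
#' @export
callDifferential <- function(fold, threshold = 2) {
    abs(fold) >= threshold
}

#' Per-gene expression-balance table across two samples
#'
#' Normalizes each peak by its sample's reference-gene factor, computes
#' the asset/variant balance per sample, the signed cross-sample fold and
#' the differential call. Balances are reported at one decimal; the fold
#' is computed from the reported (one-decimal) balances, matching how such
#' tables are printed.
#'
#' @param peaks data.frame with columns \code{gene}, \code{sample},
#'   \code{species} ("asset" or "variant"), \code{size}, \code{concentration}.
#' @param referenceFactors named numeric: reference-gene factor per sample.
#' @param caseSample,controlSample the two sample names; fold =
#'   case/control under the signed convention.
#' @param threshold differential-call boundary.
#' @return data.frame: gene, balance_control, balance_case, fold,
#'   differential.
#' @export
balanceTable <- function(peaks, referenceFactors, caseSample,
                         controlSample, threshold = 2) {
    need <- c("gene", "sample", "species", "concentration")
    if (!all(need %in% names(peaks)))
        stop("peaks table needs columns: ", paste(need, collapse = ", "))
    rows <- lapply(split(peaks, peaks$gene), function(pg) {
        bal <- vapply(c(controlSample, caseSample), function(smp) {
            ps <- pg[pg$sample == smp, ]
            a <- ps$concentration[ps$species == "asset"]
            v <- ps$concentration[ps$species == "variant"]
            if (length(a) != 1L || length(v) != 1L)
                stop("gene '", pg$gene[1L], "': expected one asset and one ",
                     "variant peak in sample '", smp, "'")
            f <- referenceFactors[[smp]]
            balanceRatio(normalizeConcentration(a, f),
                         normalizeConcentration(v, f))
        }, numeric(1))
        fold <- if (any(is.na(bal))) NA_real_
                else signedFold(bal[2L], bal[1L])
        data.frame(gene = pg$gene[1L],
                   balance_control = bal[1L], balance_case = bal[2L],
                   fold = fold,
                   differential = if (is.na(fold)) NA
                                  else callDifferential(fold, threshold))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

# printed primer/stuffer sequences for the ligation-probe assay
.FWD_PRIMER <- "GGGTAGGCTAAGGGTAGGA"
.STUFFER <- "CCGTTGCCAGTCTGCTCAGACCTCCCTCGCGCCATCAG"
.REV_PRIMER <- "TCTAGATTGGATCTTGCTGGCAC"

#' Design a ligation probe pair against an exon junction
#'
#' The left probe is forward-primer site + 38-nt stuffer + the upstream
#' target arm; the right probe (5'-phosphorylated) is the downstream
#' target arm + reverse-primer site. The two arms abut the junction with
#' no gap, so ligation occurs only when both hybridize contiguously on the
#' targeted variant.
#'
#' @param upstreamArm sequence 5' of the junction (its last
#'   \code{armLength} nt become the left arm).
#' @param downstreamArm sequence 3' of the junction (its first
#'   \code{armLength} nt become the right arm).
#' @param armLength arm length in nt, default 20.
#' @return list: left_probe, right_probe, right_phosphorylated,
#'   amplicon_length.
#' @export
designLigationProbes <- function(upstreamArm, downstreamArm,
                                 armLength = 20L) {
    upstreamArm <- as.character(upstreamArm)
    downstreamArm <- as.character(downstreamArm)
    if (nchar(upstreamArm) < armLength || nchar(downstreamArm) < armLength)
        stop("junction arms shorter than armLength (", armLength, " nt)")
    up <- substr(upstreamArm, nchar(upstreamArm) - armLength + 1L,
                 nchar(upstreamArm))
    down <- substr(downstreamArm, 1L, armLength)
    list(left_probe = paste0(.FWD_PRIMER, .STUFFER, up),
         right_probe = paste0(down, .REV_PRIMER),
         right_phosphorylated = TRUE,
         amplicon_length = nchar(.FWD_PRIMER) + nchar(.STUFFER) +
             2L * armLength + nchar(.REV_PRIMER))
}
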