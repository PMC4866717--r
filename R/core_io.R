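#' Construct a marker track
#'
#' A marker track holds the per-marker measurements for one sample on one
#' chromosome: position, B allele frequency (BAF), Log R Ratio (LRR), the
#' called genotype and the population alternate-allele frequency. It is the
#' common currency of the package: the VCF reader produces tracks, the
#' simulator generates them, and both the aneuploidy screen and the CNV
#' caller consume them.
#'
#' @param chrom Chromosome identifier (scalar character).
#' @param pos Integer vector of 1-based positions, strictly increasing.
#' @param baf Numeric vector of B allele frequencies in `[0, 1]`; `NA` marks
#'   a missing reading.
#' @param lrr Numeric vector of Log R Ratios (log2 scale, unbounded); `NA`
#'   marks a missing reading. May be all-`NA` for BAF-only calling.
#' @param gt Character vector of genotypes, one of `"RR"`, `"RA"`, `"AA"` or
#'   `NA` for a missing call. A marker with a called genotype but missing
#'   BAF is demoted to fully missing (conservative).
#' @param alt_freq Numeric vector of alternate (B) allele frequencies in
#'   `[0, 1]`, used to form genotype priors.
#'
#' @return A `data.frame` of class `"marker_track"` with columns
#'   `chrom`, `pos`, `baf`, `lrr`, `gt`, `alt_freq`.
#' @export
marker_track <- function(chrom, pos, baf, lrr, gt, alt_freq) {
  n <- length(pos)
  stopifnot(length(chrom) == 1L, length(baf) == n, length(lrr) == n,
            length(gt) == n, length(alt_freq) == n)
  if (n > 1 && any(diff(pos) <= 0))
    stop("positions must be strictly increasing within a chromosome")
  if (any(!is.na(baf) & (baf < 0 | baf > 1)))
    stop("BAF values must lie in [0, 1] or be NA")
  if (any(!is.na(alt_freq) & (alt_freq < 0 | alt_freq > 1)))
    stop("alt_freq values must lie in [0, 1]")
  bad_gt <- !is.na(gt) & !gt %in% c("RR", "RA", "AA")
  if (any(bad_gt)) stop("genotypes must be RR, RA, AA or NA")
  # missing BAF and missing genotype co-occur
  miss <- is.na(baf) | is.na(gt)
  baf[miss] <- NA_real_
  gt[miss] <- NA_character_
  out <- data.frame(chrom = chrom, pos = as.integer(pos), baf = baf,
                    lrr = lrr, gt = gt, alt_freq = alt_freq,
                    stringsAsFactors = FALSE)
  class(out) <- c("marker_track", "data.frame")
  out
}

#' Read marker tracks from a VCF file
#'
#' Reads per-sample BAF and LRR FORMAT fields plus genotypes from a VCF (or
#' bgzipped VCF) and returns one [marker_track()] per chromosome.
#' Non-biallelic records are skipped and counted. The alternate allele
#' frequency is taken, in order of preference, from a configurable INFO
#' field, from cohort genotype counts across all samples in the file, or
#' from the query sample's own genotypes.
#'
#' @param path Path to a VCF/BCF file with per-sample FORMAT fields carrying
#'   BAF and LRR values.
#' @param sample Sample name to extract; must be present in the file.
#' @param regions Optional character vector of regions to keep, each
#'   either a chromosome name (`"chr1"`) or a range
#'   (`"chr1:5000-100000"`, 1-based inclusive).
#' @param baf_field,lrr_field FORMAT field names (defaults `"BAF"`,
#'   `"LRR"`); configurable to tolerate dialects such as `"B_AF"`.
#' @param af_field INFO field name to read allele frequencies from
#'   (default `"AF"`); set `NULL` to force computation from genotypes.
#'
#' @return A named list of `marker_track` objects, one per chromosome, each
#'   sorted by position, with attribute `n_skipped` giving the number of
#'   non-biallelic records dropped.
#' @export
read_markers <- function(path, sample, regions = NULL,
                         baf_field = "BAF", lrr_field = "LRR",
                         af_field = "AF") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (!sample %in% samples)
    stop("sample '", sample, "' not found in ", path)
  fmt <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE)))
  if (!baf_field %in% fmt)
    stop("FORMAT field '", baf_field, "' not present in ", path)
  has_lrr <- lrr_field %in% fmt
  if (!has_lrr)
    warning("FORMAT field '", lrr_field,
            "' not present; LRR set to missing (BAF-only calling)")

  biall <- vcfR::is.biallelic(vcf)
  n_skipped <- sum(!biall)
  keep <- biall
  if (!is.null(regions)) {
    chm <- vcf@fix[, "CHROM"]
    ps <- as.integer(vcf@fix[, "POS"])
    in_any <- rep(FALSE, length(chm))
    for (rg in regions) {
      if (grepl(":", rg, fixed = TRUE)) {
        ch <- sub(":.*$", "", rg)
        bounds <- as.numeric(strsplit(sub("^.*:", "", rg), "-")[[1]])
        in_any <- in_any |
          (chm == ch & ps >= bounds[1] & ps <= bounds[2])
      } else {
        in_any <- in_any | chm == rg
      }
    }
    keep <- keep & in_any
  }
  vcf <- vcf[keep, ]

  chrom <- vcf@fix[, "CHROM"]
  pos <- as.integer(vcf@fix[, "POS"])
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  baf <- suppressWarnings(
    as.numeric(vcfR::extract.gt(vcf, element = baf_field)[, sample]))
  lrr <- if (has_lrr) suppressWarnings(
    as.numeric(vcfR::extract.gt(vcf, element = lrr_field)[, sample]))
  else rep(NA_real_, length(pos))

  gt <- .gt_to_class(gt_raw[, sample])

  af <- NULL
  if (!is.null(af_field)) {
    af <- suppressWarnings(
      vcfR::extract.info(vcf, element = af_field, as.numeric = TRUE))
    if (all(is.na(af))) af <- NULL
  }
  if (is.null(af)) {
    # cohort alt-allele frequency from genotypes; falls back to the query
    # sample's own genotypes when it is the only sample
    cls <- apply(gt_raw, 2, .gt_to_class)
    if (is.null(dim(cls))) cls <- matrix(cls, ncol = ncol(gt_raw))
    n_alt <- rowSums(matrix((cls == "RA") + 2 * (cls == "AA"),
                            nrow = nrow(cls)), na.rm = TRUE)
    n_called <- rowSums(!is.na(cls))
    af <- ifelse(n_called > 0, n_alt / (2 * n_called), NA_real_)
  }
  af[is.na(af)] <- 0.5  # uninformative prior where no frequency is available

  out <- lapply(split(seq_along(pos), chrom), function(i) {
    i <- i[order(pos[i])]
    marker_track(chrom[i][1], pos[i], baf[i], lrr[i], gt[i], af[i])
  })
  attr(out, "n_skipped") <- n_skipped
  out
}

.gt_to_class <- function(g) {
  g <- gsub("|", "/", g, fixed = TRUE)
  out <- rep(NA_character_, length(g))
  out[g %in% c("0/0")] <- "RR"
  out[g %in% c("0/1", "1/0")] <- "RA"
  out[g %in% c("1/1")] <- "AA"
  out
}

#' Genotype priors from an allele frequency
#'
#' Expands a site alternate-allele frequency `q` into prior probabilities of
#' the three diploid genotypes under Hardy-Weinberg proportions:
#' `f_RR = (1-q)^2`, `f_RA = 2q(1-q)`, `f_AA = q^2`.
#'
#' @param alt_freq Alternate allele frequency, in `[0, 1]`. Vectorized.
#' @return A list with numeric components `f_rr`, `f_ra`, `f_aa`, each the
#'   length of `alt_freq`, summing to 1 elementwise.
#' @examples
#' genotype_priors(0.1)  # (0.81, 0.18, 0.01)
#' @export
genotype_priors <- function(alt_freq) {
  if (any(is.na(alt_freq)) || any(alt_freq < 0 | alt_freq > 1))
    stop("alt_freq must lie in [0, 1]")
  q <- alt_freq
  list(f_rr = (1 - q)^2, f_ra = 2 * q * (1 - q), f_aa = q^2)
}

#' Smooth LRR values by a centered moving average
#'
#' LRR is substantially noisier than BAF and, when the noise is random
#' rather than systematic, can be cleaned by low-pass filtering. This
#' replaces each LRR value by the mean of the non-missing values in a
#' centered window of `window` markers. BAF is untouched.
#'
#' @param track A [marker_track()].
#' @param window Odd positive integer, number of markers in the window.
#' @return The track with smoothed `lrr`.
#' @export
smooth_lrr <- function(track, window) {
  if (window < 1 || window %% 2 == 0)
    stop("window must be an odd positive integer")
  if (window == 1) return(track)
  lrr <- track$lrr
  val <- ifelse(is.na(lrr), 0, lrr)
  n_ok <- as.numeric(!is.na(lrr))
  k <- rep(1, window)
  # centered moving sums with edge truncation
  sums <- stats::filter(val, k, sides = 2)
  cnts <- stats::filter(n_ok, k, sides = 2)
  # stats::filter returns NA at the edges; recompute there with cumsums
  n <- length(lrr)
  half <- (window - 1L) %/% 2L
  cs_v <- cumsum(c(0, val))
  cs_n <- cumsum(c(0, n_ok))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  sums_all <- cs_v[hi + 1L] - cs_v[lo]
  cnts_all <- cs_n[hi + 1L] - cs_n[lo]
  out <- ifelse(cnts_all > 0, sums_all / cnts_all, NA_real_)
  out[is.na(lrr)] <- NA_real_  # do not invent readings at missing sites
  track$lrr <- out
  track
}

#' Write called segments to a tab-delimited file
#'
#' @param segments A data.frame of segments as produced by [call_cnv()] or
#'   [call_cnv_pair()]: columns `chrom`, `start`, `end`, one or two
#'   copy-number columns (`cn`, or `cn_query`/`cn_control`), `quality`,
#'   `n_markers`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_segments <- function(segments, path) {
  cn_cols <- intersect(c("cn", "cn_query", "cn_control"), names(segments))
  cols <- c("chrom", "start", "end", cn_cols, "quality", "n_markers")
  stopifnot(all(cols %in% names(segments)))
  seg <- segments[order(segments$chrom, segments$start), cols, drop = FALSE]
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, ]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
      stop("overlapping segments on chromosome ", ch)
  }
  utils::write.table(seg, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read segments written by [write_segments()]
#'
#' @param path Path to a segment TSV.
#' @return A data.frame of segments.
#' @export
read_segments <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(chrom = "character"),
                    stringsAsFactors = FALSE)
}

#' Write marker tracks to a plain-text VCF
#'
#' Writes a minimal VCFv4.2 with FORMAT fields GT, BAF and LRR and INFO/AF,
#' so that simulated data exercise the same input path as real array
#' exports. One or more samples may be written on the same marker grid.
#'
#' @param tracks A single `marker_track` or named list of them (one entry
#'   per sample; all must share positions).
#' @param path Output path for the VCF text file.
#' @return Invisibly, the path.
#' @export
write_vcf_markers <- function(tracks, path) {
  if (inherits(tracks, "marker_track")) tracks <- list(SAMPLE = tracks)
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
    stop("tracks must be a named list (names are sample names)")
  t1 <- tracks[[1]]
  for (tr in tracks) stopifnot(identical(tr$pos, t1$pos))
  gt_map <- c(RR = "0/0", RA = "0/1", AA = "1/1")
  fmt_cols <- vapply(tracks, function(tr) {
    g <- ifelse(is.na(tr$gt), "./.", gt_map[tr$gt])
    b <- ifelse(is.na(tr$baf), ".", sprintf("%.4f", tr$baf))
    l <- ifelse(is.na(tr$lrr), ".", sprintf("%.4f", tr$lrr))
    paste(g, b, l, sep = ":")
  }, character(nrow(t1)))
  if (is.null(dim(fmt_cols))) fmt_cols <- matrix(fmt_cols, nrow = nrow(t1))
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(t1$chrom)),
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alternate allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=BAF,Number=1,Type=Float,Description=\"B Allele Frequency\">",
    "##FORMAT=<ID=LRR,Number=1,Type=Float,Description=\"Log R Ratio\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", names(tracks)), collapse = "\t"))
  body <- paste(t1$chrom, t1$pos, ".", "A", "C", ".", ".",
                sprintf("AF=%.4f", t1$alt_freq), "GT:BAF:LRR",
                apply(fmt_cols, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
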