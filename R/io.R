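#' Read diploid genotypes from a VCF file
#'
#' Keeps autosome-style biallelic SNPs (single-base REF and ALT) that are
#' polymorphic in the sample, optionally drops sites falling inside an
#' exclusion mask, and encodes the calls as a [hap_matrix()]. In phased
#' mode every diploid genotype is split into two haplotype rows and the
#' phase separator `|` is required; in unphased mode each site is encoded
#' as the individual's alt-allele dosage (0/1/2). Missing genotypes become
#' `NA`.
#'
#' @param path VCF file (4.x, GT field required; plain text or gzip).
#' @param mode `"phased"` or `"unphased"`.
#' @param mask optional BED mask: a path or a data.frame with columns
#'   chrom/start/end (0-based half-open). SNPs whose position overlaps a
#'   mask interval are dropped.
#' @return a [hap_matrix()].
#' @export
read_variants <- function(path, mode = c("phased", "unphased"),
                          mask = NULL) {
  mode <- match.arg(mode)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- rbind(fix)  # single-record VCFs collapse to a vector otherwise
  chrom <- fix[, "CHROM"]
  pos <- as.numeric(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  bases <- c("A", "C", "G", "T")
  keep <- ref %in% bases & alt %in% bases
  if (!is.null(mask)) {
    bed <- if (is.character(mask)) read_bed(mask) else mask
    for (j in seq_len(nrow(bed))) {
      hit <- chrom == bed[j, 1] & pos > bed[j, 2] & pos <= bed[j, 3]
      keep <- keep & !hit
    }
  }
  if (!any(keep)) stop("no biallelic SNPs left after filtering")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- rbind(gt)[keep, , drop = FALSE]
  chrom <- chrom[keep]; pos <- pos[keep]
  gt[gt %in% c(".", "./.", ".|.")] <- NA
  if (mode == "phased") {
    bad <- which(!is.na(gt) & !grepl("|", gt, fixed = TRUE))
    if (length(bad)) {
      rc <- arrayInd(bad[1], dim(gt))
      stop("phased mode but unphased genotype '", gt[bad[1]],
           "' at ", chrom[rc[1]], ":", pos[rc[1]],
           " (sample ", colnames(gt)[rc[2]], ")")
    }
    a1 <- suppressWarnings(matrix(
      as.integer(sub("\\|.*", "", gt)), nrow(gt), ncol(gt)))
    a2 <- suppressWarnings(matrix(
      as.integer(sub(".*\\|", "", gt)), nrow(gt), ncol(gt)))
    n <- ncol(gt)
    alle <- matrix(NA_integer_, 2L * n, nrow(gt))
    alle[seq(1L, 2L * n, by = 2L), ] <- t(a1)
    alle[seq(2L, 2L * n, by = 2L), ] <- t(a2)
    ids <- as.vector(rbind(paste0(colnames(gt), "_1"),
                           paste0(colnames(gt), "_2")))
  } else {
    d1 <- suppressWarnings(as.integer(sub("[|/].*", "", gt)))
    d2 <- suppressWarnings(as.integer(sub(".*[|/]", "", gt)))
    alle <- t(matrix(d1 + d2, nrow(gt), ncol(gt)))
    ids <- colnames(gt)
  }
  # polymorphic in the sample: at least two distinct observed codes
  poly <- apply(alle, 2L, function(v) length(unique(v[!is.na(v)])) >= 2L)
  if (!any(poly)) stop("no SNPs polymorphic in the sample")
  hap_matrix(alle[, poly, drop = FALSE], chrom[poly], pos[poly],
             phased = (mode == "phased"), sample_ids = ids)
}

read_bed <- function(path) {
  bed <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 3) stop("BED mask needs >= 3 columns")
  bed[, 1] <- as.character(bed[, 1])
  bed[, 2] <- as.numeric(bed[, 2])
  bed[, 3] <- as.numeric(bed[, 3])
  bed[, 1:3]
}

#' Read a genetic map
#'
#' Whitespace-delimited table with chromosome in the first column, physical
#' position (bp) in the second and cumulative map position (cM) in the last
#' column; intermediate columns (e.g. local recombination rate) are
#' ignored. A non-numeric first line is treated as a header.
#'
#' @param path map file.
#' @return data.frame with columns `chrom`, `pos_bp`, `cm`, sorted by
#'   chromosome and position.
#' @export
read_genetic_map <- function(path) {
  first <- read.table(path, header = FALSE, nrows = 1L,
                      stringsAsFactors = FALSE)
  has_header <- is.na(suppressWarnings(as.numeric(first[1, 2])))
  tab <- read.table(path, header = has_header, stringsAsFactors = FALSE)
  map <- data.frame(chrom = as.character(tab[, 1]),
                    pos_bp = as.numeric(tab[, 2]),
                    cm = as.numeric(tab[, ncol(tab)]),
                    stringsAsFactors = FALSE)
  map <- map[order(map$chrom, map$pos_bp), ]
  for (ch in unique(map$chrom)) {
    v <- map$cm[map$chrom == ch]
    if (any(diff(v) < 0))
      stop("cM positions decrease along chromosome ", ch)
  }
  rownames(map) <- NULL
  map
}

#' Interpolate genetic-map position at physical positions
#'
#' Linear interpolation between the nearest surrounding anchors; positions
#' beyond the first or last anchor are clamped to the boundary cM value.
#'
#' @param map data.frame from [read_genetic_map()].
#' @param chrom chromosome label.
#' @param pos_bp numeric vector of physical positions.
#' @return numeric vector of cM positions.
#' @export
interpolate_cm <- function(map, chrom, pos_bp) {
  sub <- map[map$chrom == chrom, ]
  if (!nrow(sub))
    stop("chromosome ", chrom, " absent from map (available: ",
         paste(unique(map$chrom), collapse = ", "), ")")
  if (nrow(sub) < 2) stop("need >= 2 map anchors on chromosome ", chrom)
  stats::approx(sub$pos_bp, sub$cm, xout = pos_bp, rule = 2,
                ties = "ordered")$y
}

#' Assign window coordinates in a distance measure
#'
#' * `bp`: the midpoint `(start_bp + end_bp) / 2` of the window's first and
#'   last SNP positions.
#' * `cm`: the genetic-map position of that midpoint, interpolated with
#'   [interpolate_cm()].
#' * `windex`: the window's 1-based ordinal among the windows of its
#'   chromosome.
#'
#' @param windows data.frame from [build_windows()].
#' @param measure `"bp"`, `"cm"` or `"windex"`.
#' @param map genetic map (required for `"cm"`).
#' @return numeric vector `z`, one coordinate per window.
#' @export
window_coordinates <- function(windows, measure = c("bp", "cm", "windex"),
                               map = NULL) {
  measure <- match.arg(measure)
  mid <- (windows$start_bp + windows$end_bp) / 2
  switch(measure,
    bp = mid,
    windex = as.numeric(windows$chrom_windex),
    cm = {
      if (is.null(map)) stop("distance measure 'cm' requires a genetic map")
      vapply(seq_len(nrow(windows)),
             function(i) interpolate_cm(map, windows$chrom[i], mid[i]),
             numeric(1))
    })
}

scan_table_cols <- c("chrom", "win_id", "start_bp", "end_bp", "mid",
                     "n_snps", "n_obs", "n_distinct", "h12_or_g123",
                     "h2h1_or_g2g1", "T", "m_hat_T", "lambda", "m_hat",
                     "log10_A_hat", "eps_hat")

#' Write the per-window scan results table
#'
#' Fixed 16-column tab-separated schema; floats are rendered with 6
#' significant digits and rows are sorted by chromosome then window index,
#' so re-running a scan reproduces the file byte for byte.
#'
#' @param rows data.frame from [hfs_scan()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(rows, path) {
  missing_cols <- setdiff(scan_table_cols, names(rows))
  if (length(missing_cols))
    stop("rows lack columns: ", paste(missing_cols, collapse = ", "))
  rows <- rows[order(rows$chrom, rows$win_id), scan_table_cols]
  fmt <- rows
  for (cn in names(fmt))
    if (is.double(fmt[[cn]])) fmt[[cn]] <- sprintf("%.6g", fmt[[cn]])
  write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a scan results table written by [write_scan_table()]
#' @param path file path.
#' @return data.frame with the fixed 16-column schema.
#' @export
read_scan_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  tab$chrom <- as.character(tab$chrom)
  tab
}
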