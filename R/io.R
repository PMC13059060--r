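#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses the GT field of a VCF into a [genotype_matrix()]. Records
#' that are not biallelic SNPs (multi-allelic sites, indels, symbolic
#' alleles) are skipped and counted. Genotype phase is ignored
#' (`0|1` is the same call as `0/1`) and any call with a missing allele
#' (`./.`, `.|0`) is treated as missing.
#'
#' @param path path to a VCF (plain text or bgzip).
#' @param verbose print the number of skipped records.
#' @return A `genotype_matrix`; attribute `n_skipped` carries the count
#'   of skipped non-SNP/multi-allelic records.
#' @export
read_genotypes <- function(path, verbose = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L) stop("VCF contains no variant records: ", path)
  if (!"FORMAT" %in% colnames(v@gt) || ncol(v@gt) < 2L)
    stop("VCF has no genotype columns: ", path)
  if (!any(grepl("(^|:)GT(:|$)", v@gt[, "FORMAT"])))
    stop("VCF FORMAT lacks a GT field: ", path)
  fix <- as.data.frame(v@fix[, c("CHROM", "POS", "REF", "ALT"),
                             drop = FALSE])
  nt <- c("A", "C", "G", "T")
  keep <- fix$REF %in% nt & fix$ALT %in% nt
  n_skipped <- sum(!keep)
  if (!any(keep)) stop("VCF contains no biallelic SNP records: ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  codes <- parse_gt_codes(gt)
  loci <- data.frame(chrom = fix$CHROM[keep],
                     pos = as.integer(fix$POS[keep]),
                     ref = fix$REF[keep], alt = fix$ALT[keep])
  if (verbose && n_skipped)
    message("read_genotypes: skipped ", n_skipped,
            " non-SNP/multi-allelic records")
  gm <- genotype_matrix(loci, colnames(gt), codes)
  attr(gm, "n_skipped") <- n_skipped
  gm
}

# "0/1", "0|1", "1/0" -> 1; "./.", ".|0", NA -> NA; phase-insensitive.
parse_gt_codes <- function(gt) {
  u <- unique(as.vector(gt))
  code1 <- vapply(u, function(s) {
    if (is.na(s)) return(NA_integer_)
    al <- strsplit(sub(":.*$", "", s), "[/|]")[[1]]
    if (length(al) != 2L || any(al == ".")) return(NA_integer_)
    sum(as.integer(al))
  }, integer(1))
  matrix(code1[match(as.vector(gt), u)], nrow = nrow(gt),
         dimnames = dimnames(gt))
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCF 4.2 file with a GT-only FORMAT, suitable for round-trip
#' through [read_genotypes()].
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @param contig_lengths optional named vector used to emit
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, contig_lengths = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  hdr <- c("##fileformat=VCFv4.2", "##source=slrscan")
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths),
                          as.integer(contig_lengths)))
  hdr <- c(hdr,
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples), collapse = "\t"))
  gt_str <- c("0/0", "0/1", "1/1")[gm$codes + 1L]
  gt_str[is.na(gt_str)] <- "./."
  gt <- matrix(gt_str, nrow = nrow(gm$loci))
  body <- paste(gm$loci$chrom, gm$loci$pos, ".", gm$loci$ref, gm$loci$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated file with header; columns `sample_id` and `sex` are
#' required, `population` and `male_class` optional. Sex tokens are
#' normalised through `sex_aliases` before validation.
#'
#' @param path TSV path.
#' @param sex_aliases named character vector mapping input tokens to
#'   "F"/"M" (case-insensitive match on names).
#' @return data.frame of class `sample_sheet` with columns `sample_id`,
#'   `sex`, `population`, `male_class`.
#' @export
read_sample_sheet <- function(path,
                              sex_aliases = c(f = "F", female = "F",
                                              m = "M", male = "M")) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("sample_id", "sex") %in% names(d)))
    stop("sample sheet must have columns sample_id and sex")
  sample_sheet(d$sample_id, d$sex,
               population = d$population,
               male_class = d$male_class,
               sex_aliases = sex_aliases)
}

#' Construct a sample sheet
#'
#' @param sample_id character vector of unique sample ids.
#' @param sex sex labels; normalised through `sex_aliases` to "F"/"M".
#' @param population optional population labels.
#' @param male_class optional labels in \{"M1", "M2", "unknown"\} (NA
#'   allowed); only meaningful for males.
#' @param sex_aliases see [read_sample_sheet()].
#' @return data.frame of class `sample_sheet`.
#' @export
sample_sheet <- function(sample_id, sex, population = NULL,
                         male_class = NULL,
                         sex_aliases = c(f = "F", female = "F",
                                         m = "M", male = "M")) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id in sample sheet")
  key <- tolower(as.character(sex))
  sex_n <- unname(sex_aliases[key])
  bad <- is.na(sex_n) | !sex_n %in% c("F", "M")
  if (any(bad))
    stop("unknown sex token(s): ", paste(unique(sex[bad]), collapse = ", "))
  mc <- male_class %||% rep(NA_character_, length(sample_id))
  mc[!is.na(mc) & mc == ""] <- NA_character_
  if (any(!is.na(mc) & !mc %in% c("M1", "M2", "unknown")))
    stop("male_class must be M1, M2, unknown or NA")
  d <- data.frame(sample_id = sample_id, sex = sex_n,
                  population = population %||% rep(NA_character_,
                                                   length(sample_id)),
                  male_class = mc, stringsAsFactors = FALSE)
  class(d) <- c("sample_sheet", "data.frame")
  d
}

# Split sample ids by sex, enforcing at least one of each for
# sex-contrast operations.
split_sexes <- function(sheet, require_both = TRUE) {
  stopifnot(inherits(sheet, "sample_sheet") || is.data.frame(sheet))
  f <- sheet$sample_id[sheet$sex == "F"]
  m <- sheet$sample_id[sheet$sex == "M"]
  if (require_both && (!length(f) || !length(m)))
    stop("sex-contrast operation needs at least one female and one male")
  list(F = f, M = m)
}

# Check that every sample-sheet id exists in the data; the sheet may
# cover a subset of the data samples (sex-contrast operations then use
# only that subset), but ids unknown to the data are an error.
check_samples_match <- function(samples, sheet, exact = FALSE) {
  extra <- setdiff(sheet$sample_id, samples)
  missing_ <- if (exact) setdiff(samples, sheet$sample_id) else character(0)
  if (length(missing_) || length(extra))
    stop("sample sheet does not match data samples (missing: ",
         paste(missing_, collapse = ","), "; extra: ",
         paste(extra, collapse = ","), ")")
  invisible(TRUE)
}

#' Read a per-window depth table
#'
#' BED-like TSV with header: columns `chrom`, `start`, `end` (0-based
#' half-open) followed by one numeric column per sample giving mean
#' read depth in the window. Rows may arrive in any order; they are
#' sorted and the grid validated as a non-overlapping tiling.
#'
#' @param path TSV path.
#' @return An object of class `depth_table`: list with `windows`
#'   (chrom/start/end/index data.frame), `samples`, and `depth`
#'   (windows x samples matrix).
#' @export
read_depth <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(d) < 4L || !all(c("chrom", "start", "end") %in% names(d)))
    stop("depth table needs chrom, start, end plus sample columns")
  samples <- setdiff(names(d), c("chrom", "start", "end"))
  depth_table(d[, c("chrom", "start", "end")],
              as.matrix(d[, samples, drop = FALSE]))
}

#' Construct a depth table
#'
#' @param windows data.frame with `chrom`, `start`, `end` (0-based
#'   half-open tiling grid).
#' @param depth numeric windows x samples matrix of mean depths; column
#'   names are the sample ids.
#' @return An object of class `depth_table`.
#' @export
depth_table <- function(windows, depth) {
  windows <- as.data.frame(windows)[, c("chrom", "start", "end")]
  depth <- as.matrix(depth)
  if (is.null(colnames(depth))) stop("depth matrix needs sample names")
  if (nrow(depth) != nrow(windows))
    stop("depth rows do not match windows")
  if (any(depth < 0, na.rm = TRUE)) stop("negative depth values")
  o <- order(windows$chrom, windows$start)
  windows <- windows[o, , drop = FALSE]
  depth <- depth[o, , drop = FALSE]
  validate_window_grid(windows)
  windows$index <- seq_len(nrow(windows))
  rownames(windows) <- NULL
  structure(list(windows = windows, samples = colnames(depth),
                 depth = depth), class = "depth_table")
}

#' @export
print.depth_table <- function(x, ...) {
  cat(sprintf("depth_table: %d windows x %d samples\n",
              nrow(x$windows), length(x$samples)))
  invisible(x)
}

#' Write a depth table as BED-like TSV
#'
#' @param dt a [depth_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_depth <- function(dt, path) {
  stopifnot(inherits(dt, "depth_table"))
  out <- cbind(dt$windows[, c("chrom", "start", "end")],
               as.data.frame(dt$depth))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a window track
#'
#' Tracks are data.frames on a window grid (`chrom`, `start`, `end`)
#' with one named numeric column per statistic; missing values are
#' written as `NA`.
#'
#' @param track window-track data.frame.
#' @param path TSV path.
#' @return `path` (write) or the track data.frame (read).
#' @export
write_tracks <- function(track, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(track)))
  write.table(track, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write regions as BED
#'
#' 0-based half-open BED with columns chrom, start, end, label
#' (name), score. An empty region set yields an empty file.
#'
#' @param regions data.frame with `chrom`, `start`, `end` and optional
#'   `label`, `score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  if (is.null(regions) || !nrow(regions)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lab <- regions$label %||% rep(".", nrow(regions))
  sc <- regions$score %||% rep(NA_real_, nrow(regions))
  sc <- ifelse(is.na(sc), ".", format(sc, digits = 6, trim = TRUE))
  writeLines(paste(regions$chrom, format(regions$start, scientific = FALSE,
                                         trim = TRUE),
                   format(regions$end, scientific = FALSE, trim = TRUE),
                   lab, sc, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_regions
#' @export
read_regions <- function(path) {
  lines <- readLines(path)
  if (!length(lines))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), label = character(0),
                      score = numeric(0)))
  d <- read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  names(d)[1:3] <- c("chrom", "start", "end")
  if (ncol(d) >= 4) names(d)[4] <- "label"
  if (ncol(d) >= 5) {
    names(d)[5] <- "score"
    d$score <- suppressWarnings(as.numeric(d$score))
  }
  d
}

# Region row constructor used by callers that assemble region sets.
region_df <- function(chrom = character(0), start = numeric(0),
                      end = numeric(0), label = character(0),
                      score = numeric(0)) {
  d <- data.frame(chrom = chrom, start = start, end = end,
                  label = label, score = score,
                  stringsAsFactors = FALSE)
  if (nrow(d) && any(d$start >= d$end)) stop("region start must be < end")
  d
}
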