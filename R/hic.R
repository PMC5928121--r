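#' Read genomic interval sets in the dialects of the pipeline
#'
#' Supported dialects:
#' * `"bed"`: 3+ column BED (0-based half-open).
#' * `"arrowhead"`: Arrowhead domain/loop list TSV with header columns
#'   `chr1 x1 x2 chr2 y1 y2 ...` (0-based half-open); both coordinate
#'   pairs of each record are extracted and identical pairs deduplicated,
#'   so a domain list yields one interval per record and a loop list its
#'   two anchors.
#' * `"hot-fasta-headers"`: FASTA whose headers carry `chr:start-end`
#'   locus strings (1-based closed); only headers are parsed.
#'
#' All dialects are normalized into a [GenomicRanges::GRanges] (the
#' package-wide 1-based closed container), so the same intervals read via
#' two dialects compare identical.
#'
#' @param path Input file.
#' @param dialect One of `"bed"`, `"arrowhead"`, `"hot-fasta-headers"`.
#' @param role Optional role tag (`"HOT"`, `"loop"`) stored in
#'   `mcols()$role`.
#' @return A `GRanges`, sorted within chromosomes.
#' @export
read_intervals <- function(path, dialect = c("bed", "arrowhead",
                                             "hot-fasta-headers"),
                           role = NA_character_) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty interval file: ", path)
    return(empty_intervals(role))
  }
  if (dialect == "bed") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 3L)
    if (length(bad)) {
      stop("malformed BED record at line ", bad[1], " of ", path)
    }
    chrom <- vapply(fields, `[[`, "", 1L)
    start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
    end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    if (anyNA(start0) || anyNA(end0)) {
      stop("non-numeric BED coordinates at line ",
           which(is.na(start0) | is.na(end0))[1], " of ", path)
    }
    gr <- make_intervals(chrom, start0 + 1, end0, role)
  } else if (dialect == "arrowhead") {
    first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    has_header <- any(tolower(first[1]) %in% c("chr1", "chrom1", "#chr1"))
    body <- if (has_header) lines[-1] else lines
    if (!length(body)) {
      warning("empty interval file: ", path)
      return(empty_intervals(role))
    }
    fields <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 6L)
    if (length(bad)) {
      stop("malformed Arrowhead record at line ",
           bad[1] + has_header, " of ", path)
    }
    get <- function(i) vapply(fields, `[[`, "", i)
    num <- function(i) suppressWarnings(as.numeric(get(i)))
    chrom1 <- get(1); x1 <- num(2); x2 <- num(3)
    chrom2 <- get(4); y1 <- num(5); y2 <- num(6)
    if (anyNA(x1) || anyNA(x2) || anyNA(y1) || anyNA(y2)) {
      stop("non-numeric Arrowhead coordinates in ", path)
    }
    gr <- make_intervals(c(chrom1, chrom2), c(x1, y1) + 1, c(x2, y2), role)
    gr <- unique(gr)
  } else {
    headers <- grep("^>", lines, value = TRUE)
    if (!length(headers)) {
      warning("no FASTA headers in: ", path)
      return(empty_intervals(role))
    }
    m <- regmatches(headers,
                    regexec("([^>\\s:]+):(\\d+)-(\\d+)", headers))
    bad <- which(lengths(m) != 4L)
    if (length(bad)) {
      stop("FASTA header without chr:start-end locus at record ", bad[1],
           " of ", path)
    }
    chrom <- vapply(m, `[[`, "", 2L)
    start1 <- as.numeric(vapply(m, `[[`, "", 3L))
    end1 <- as.numeric(vapply(m, `[[`, "", 4L))
    gr <- make_intervals(chrom, start1, end1, role)
  }
  GenomicRanges::sort(gr)
}

make_intervals <- function(chrom, start1, end1, role) {
  if (any(end1 < start1)) {
    stop("interval with end < start encountered")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start1, end = end1))
  S4Vectors::mcols(gr)$role <- role
  gr
}

empty_intervals <- function(role = NA_character_) {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr)$role <- character(0)
  gr
}

#' Read a chromosome-sizes table
#'
#' Two-column TSV of chromosome name and length in bp.
#'
#' @param path Input file.
#' @return Named numeric vector of chromosome sizes.
#' @export
read_genome_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "size"),
                   colClasses = c("character", "numeric"))
  setNames(df$size, df$chrom)
}

#' Construct a binned contact matrix object
#'
#' @param mat Square symmetric non-negative matrix of normalized contact
#'   signal.
#' @param bin_size Bin width in bp (default 50000).
#' @param chrom Chromosome label.
#' @return An object of class `contact_bins`.
#' @export
contact_bins <- function(mat, bin_size = 50000, chrom = "chr1") {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("matrix must be square")
  if (any(mat < 0)) stop("contact signal must be non-negative")
  if (max(abs(mat - t(mat))) > 1e-8 * max(1, max(mat))) {
    stop("matrix must be symmetric")
  }
  structure(list(signal = mat, bin_size = bin_size, chrom = chrom),
            class = "contact_bins")
}

#' @export
print.contact_bins <- function(x, ...) {
  cat("Binned contact matrix:", nrow(x$signal), "x", nrow(x$signal),
      "bins of", x$bin_size, "bp on", x$chrom, "\n")
  invisible(x)
}

#' Read a binned contact matrix from text
#'
#' @param path Dense tab-separated matrix, or sparse 3-column
#'   (`i j value`, 1-based bin indices) TSV.
#' @param format `"dense"` or `"sparse"`.
#' @param n_bins Required for sparse input.
#' @inheritParams contact_bins
#' @return A `contact_bins` object.
#' @export
read_contact_bins <- function(path, format = c("dense", "sparse"),
                              bin_size = 50000, chrom = "chr1",
                              n_bins = NULL) {
  format <- match.arg(format)
  if (format == "dense") {
    mat <- as.matrix(read.table(path, sep = "\t", header = FALSE))
    dimnames(mat) <- NULL
  } else {
    df <- read.table(path, sep = "\t", header = FALSE,
                     col.names = c("i", "j", "value"))
    if (is.null(n_bins)) n_bins <- max(df$i, df$j)
    mat <- matrix(0, n_bins, n_bins)
    mat[cbind(df$i, df$j)] <- df$value
    mat[cbind(df$j, df$i)] <- df$value
  }
  contact_bins(mat, bin_size = bin_size, chrom = chrom)
}

#' Local contact-decay exponents by windowed log-log regression
#'
#' The probability of Hi-C contacts is locally proportional to
#' \eqn{s^{-\alpha}} in the linear separation \eqn{s}. For each window
#' `i`, the signal to its `flank` nearest windows on each side (self
#' contacts discarded, both sides pooled) is regressed on separation on
#' log-log axes; the slope estimates the local decay exponent
#' \eqn{\alpha_i} (negative; more negative = less compact). Zero-signal
#' pairs are dropped from the regression (optionally replaced by a
#' pseudo-count), and windows with fewer than `min_points` usable points
#' yield a missing estimate.
#'
#' @param bins A [contact_bins()] object.
#' @param flank Windows used on each side (default 20).
#' @param min_points Minimum usable points per regression (default 5).
#' @param pseudo Optional pseudo-count added to zero signal instead of
#'   dropping it (default `NULL` = drop).
#' @return An object of class `decay_profile`: data frame with columns
#'   `window`, `start`, `end`, `alpha`, `n_points`, plus attributes
#'   `bin_size` and `chrom`.
#' @export
contact_decay <- function(bins, flank = 20, min_points = 5, pseudo = NULL) {
  if (!inherits(bins, "contact_bins")) stop("'bins' must be contact_bins")
  M <- bins$signal
  n <- nrow(M)
  if (n < 2 * flank + 1) {
    stop("matrix too small: need at least 2*flank + 1 = ", 2 * flank + 1,
         " bins for interior windows")
  }
  log_s <- log(seq_len(flank) * bins$bin_size)
  alpha <- rep(NA_real_, n)
  npts <- integer(n)
  for (i in seq_len(n)) {
    d_left <- seq_len(min(flank, i - 1))
    d_right <- seq_len(min(flank, n - i))
    x <- c(log_s[d_left], log_s[d_right])
    y <- c(M[i, i - d_left], M[i, i + d_right])
    if (!is.null(pseudo)) y[y == 0] <- pseudo
    keep <- y > 0
    x <- x[keep]
    y <- log(y[keep])
    npts[i] <- length(x)
    if (length(x) < min_points || length(unique(x)) < 2) next
    mx <- mean(x)
    alpha[i] <- sum((x - mx) * (y - mean(y))) / sum((x - mx)^2)
  }
  out <- data.frame(window = seq_len(n),
                    start = (seq_len(n) - 1) * bins$bin_size,
                    end = seq_len(n) * bins$bin_size,
                    alpha = alpha, n_points = npts)
  attr(out, "bin_size") <- bins$bin_size
  attr(out, "chrom") <- bins$chrom
  class(out) <- c("decay_profile", "data.frame")
  out
}

#' Write a decay profile as bedGraph-style TSV
#'
#' @param profile A [contact_decay()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decay_profile <- function(profile, path) {
  df <- data.frame(chrom = attr(profile, "chrom"), start = profile$start,
                   end = profile$end, alpha = profile$alpha)
  write.table(df, path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Enrichment of interval midpoints inside loop intervals
#'
#' Counts the HOT intervals whose midpoint falls inside any merged loop
#' interval and compares against a binomial null in which each midpoint
#' lands in the merged loop footprint with probability
#' footprint / genome size. The p-value is the upper binomial tail
#' \eqn{P(X \ge \mathrm{observed})}.
#'
#' @param hots `GRanges` of HOT regions.
#' @param loops `GRanges` of loop (or domain) intervals.
#' @param genome_sizes Named vector of chromosome sizes covering every
#'   chromosome present in `hots`.
#' @param rule `"midpoint"` (default; HOTs are sub-kilobase, so midpoint
#'   containment is effectively any-overlap) or `"any"` (any overlap).
#' @return An object of class `enrichment_result`: list with `n_hots`,
#'   `n_overlapping`, `n_expected`, `p_null`, `p_value`.
#' @export
hot_loop_enrichment <- function(hots, loops, genome_sizes,
                                rule = c("midpoint", "any")) {
  rule <- match.arg(rule)
  hot_chroms <- unique(as.character(GenomicRanges::seqnames(hots)))
  missing_chroms <- setdiff(hot_chroms, names(genome_sizes))
  if (length(missing_chroms)) {
    stop("chromosome(s) absent from genome_sizes: ",
         paste(missing_chroms, collapse = ", "))
  }
  merged <- GenomicRanges::reduce(loops)
  merged <- merged[as.character(GenomicRanges::seqnames(merged)) %in%
                     names(genome_sizes)]
  footprint <- sum(as.numeric(GenomicRanges::width(merged)))
  p_null <- footprint / sum(as.numeric(genome_sizes))
  n_hots <- length(hots)
  query <- if (rule == "midpoint") {
    GenomicRanges::resize(hots, width = 1, fix = "center")
  } else {
    hots
  }
  n_overlap <- sum(IRanges::overlapsAny(query, merged))
  p_value <- if (n_hots == 0) {
    NA_real_
  } else {
    pbinom(n_overlap - 1, n_hots, p_null, lower.tail = FALSE)
  }
  structure(list(n_hots = n_hots, n_overlapping = n_overlap,
                 n_expected = n_hots * p_null, p_null = p_null,
                 p_value = p_value, rule = rule),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Loop enrichment:", x$n_overlapping, "of", x$n_hots,
      "intervals in loops vs", round(x$n_expected, 1),
      "expected (binomial P =", format(x$p_value, digits = 3), ")\n")
  invisible(x)
}

#' Serialize an enrichment result as JSON
#'
#' @param x An [hot_loop_enrichment()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Compare decay exponents at intervals against the genome-wide set
#'
#' Sample A is every window with a decay estimate; sample B is the subset
#' of windows containing the midpoint of at least one query interval.
#' Returns both means and a Welch two-sample t test
#' (Welch-Satterthwaite degrees of freedom) for the difference.
#'
#' @param profile A [contact_decay()] result.
#' @param intervals `GRanges` of query intervals (e.g. HOTs) on the same
#'   chromosome as the profile.
#' @return List with `mean_all`, `mean_at`, `n_all`, `n_at`, `statistic`,
#'   `df`, `p_value`, `conf_int` (95\% CI for mean_all - mean_at) and
#'   `degenerate` (TRUE when both samples have zero variance and the test
#'   is undefined).
#' @export
decay_at_intervals <- function(profile, intervals) {
  chrom <- attr(profile, "chrom")
  on_chrom <- intervals[as.character(
    GenomicRanges::seqnames(intervals)) == chrom]
  mids0 <- floor((GenomicRanges::start(on_chrom) - 1 +
                    GenomicRanges::end(on_chrom)) / 2)  # 0-based midpoint
  win <- findInterval(mids0, profile$start)
  win <- win[win >= 1 & win <= nrow(profile)]
  a <- profile$alpha[!is.na(profile$alpha)]
  b <- profile$alpha[unique(win)]
  b <- b[!is.na(b)]
  if (!length(b)) stop("no decay estimates at the query intervals")
  if (sd(a) == 0 && sd(b) == 0) {
    return(list(mean_all = mean(a), mean_at = mean(b),
                n_all = length(a), n_at = length(b),
                statistic = NA_real_, df = NA_real_,
                p_value = if (mean(a) == mean(b)) 1 else NA_real_,
                conf_int = c(NA_real_, NA_real_),
                difference = mean(a) - mean(b), degenerate = TRUE))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(mean_all = mean(a), mean_at = mean(b),
       n_all = length(a), n_at = length(b),
       statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, conf_int = unname(tt$conf.int),
       difference = mean(a) - mean(b), degenerate = FALSE)
}
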