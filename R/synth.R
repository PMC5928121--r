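#' Synthetic binned contact matrix with known decay structure
#'
#' Generates a power-law-decaying contact matrix
#' \eqn{signal(i,j) = |i-j|^{\alpha}} with a locally varying exponent
#' (per-bin \eqn{\alpha_i}, combined for a pair as the mean of the two bin
#' values, which keeps the matrix symmetric and the per-window estimate
#' exact inside patches wider than the regression flank), multiplied by
#' log-normal noise and with Gaussian-bump loop peaks superimposed. A
#' truth record carries every generating parameter for recovery tests.
#'
#' @param n_bins Number of bins.
#' @param bin_size Bin width in bp (default 50000).
#' @param alpha_background Background decay exponent (< 0).
#' @param alpha_patches Optional list of `list(from, to, alpha)` bin-index
#'   ranges overriding the background exponent.
#' @param loop_peaks Optional list of `list(i, j, strength, width)`
#'   Gaussian bumps (width in bins, default 2).
#' @param noise_sdlog Log-normal noise sd on the log scale (0 = none).
#' @param seed Integer seed.
#' @return List with `bins` (a [contact_bins()]) and `truth`.
#' @export
synth_hic <- function(n_bins, bin_size = 50000, alpha_background = -1,
                      alpha_patches = list(), loop_peaks = list(),
                      noise_sdlog = 0, seed = 1) {
  if (alpha_background >= 0) stop("decay exponents must be negative")
  alpha_bin <- rep(alpha_background, n_bins)
  for (p in alpha_patches) {
    if (p$alpha >= 0) stop("decay exponents must be negative")
    if (p$from < 1 || p$to > n_bins || p$from > p$to) {
      stop("alpha patch range out of bounds")
    }
    alpha_bin[p$from:p$to] <- p$alpha
  }
  ii <- matrix(seq_len(n_bins), n_bins, n_bins)
  jj <- t(ii)
  sep <- abs(ii - jj)
  a_pair <- (matrix(alpha_bin, n_bins, n_bins) +
               matrix(alpha_bin, n_bins, n_bins, byrow = TRUE)) / 2
  M <- ifelse(sep == 0, 1, sep^a_pair)
  for (pk in loop_peaks) {
    if (pk$i < 1 || pk$i > n_bins || pk$j < 1 || pk$j > n_bins) {
      stop("loop peak out of bounds")
    }
    w <- pk$width %||% 2
    bump <- pk$strength *
      exp(-((ii - pk$i)^2 + (jj - pk$j)^2) / (2 * w^2)) +
      pk$strength *
        exp(-((ii - pk$j)^2 + (jj - pk$i)^2) / (2 * w^2))
    M <- M + bump
  }
  if (noise_sdlog > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    noise <- matrix(0, n_bins, n_bins)
    up <- upper.tri(noise, diag = TRUE)
    noise[up] <- rnorm(sum(up), 0, noise_sdlog)
    noise <- noise + t(noise) - diag(diag(noise))
    M <- M * exp(noise)
  }
  list(bins = contact_bins(M, bin_size = bin_size, chrom = "synthetic"),
       truth = list(alpha_bin = alpha_bin,
                    alpha_background = alpha_background,
                    alpha_patches = alpha_patches,
                    loop_peaks = loop_peaks,
                    noise_sdlog = noise_sdlog, seed = seed))
}

#' Synthetic HOT and loop interval sets with controlled enrichment
#'
#' Places `n_loops` loop intervals uniformly on the genome, merges their
#' footprint, and then places each HOT midpoint inside the merged loop
#' footprint with probability `enrichment_rho * p_null` (capped at 1,
#' where `p_null` is the footprint fraction of the genome) and uniformly
#' outside otherwise. At `enrichment_rho = 1` the marginal placement is
#' uniform and the enrichment p-value of [hot_loop_enrichment()] is
#' calibrated; larger values produce genuine enrichment. The truth record
#' carries the realized overlap count and `p_null`.
#'
#' @param n_hots Number of HOT intervals.
#' @param n_loops Number of loop intervals.
#' @param genome_sizes Named vector of chromosome sizes in bp.
#' @param enrichment_rho Enrichment factor (>= 0; 1 = null).
#' @param loop_width Loop interval width in bp (default 200000).
#' @param hot_width HOT interval width in bp (default 1000).
#' @param seed Integer seed.
#' @return List with `hots`, `loops` (both `GRanges`) and `truth`.
#' @export
synth_intervals <- function(n_hots, n_loops, genome_sizes,
                            enrichment_rho = 1, loop_width = 200000,
                            hot_width = 1000, seed = 1) {
  if (enrichment_rho < 0) stop("'enrichment_rho' must be >= 0")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  chroms <- names(genome_sizes)
  total <- sum(as.numeric(genome_sizes))

  draw_uniform <- function(n, width) {
    cs <- sample(chroms, n, replace = TRUE,
                 prob = as.numeric(genome_sizes) / total)
    starts <- floor(runif(n, 0, pmax(genome_sizes[cs] - width, 1)))
    GenomicRanges::GRanges(cs, IRanges::IRanges(start = starts + 1,
                                                width = width))
  }

  loops <- if (n_loops > 0) draw_uniform(n_loops, loop_width)
           else GenomicRanges::GRanges()
  S4Vectors::mcols(loops)$role <- if (n_loops > 0) "loop" else character(0)
  merged <- GenomicRanges::reduce(loops)
  footprint <- sum(as.numeric(GenomicRanges::width(merged)))
  p_null <- footprint / total
  p_in <- min(1, enrichment_rho * p_null)
  if (enrichment_rho > 1 && enrichment_rho * p_null > 1) {
    stop("infeasible enrichment_rho: rho * p_null = ",
         round(enrichment_rho * p_null, 3), " exceeds 1")
  }

  inside <- if (n_hots > 0) runif(n_hots) < p_in else logical(0)
  n_in <- sum(inside)
  mids <- numeric(n_hots)
  mid_chrom <- character(n_hots)
  if (n_in > 0) {
    # uniform over the merged loop footprint
    w <- as.numeric(GenomicRanges::width(merged))
    pick <- sample(length(merged), n_in, replace = TRUE, prob = w / sum(w))
    offs <- floor(runif(n_in, 0, w[pick]))
    mids[inside] <- GenomicRanges::start(merged)[pick] + offs
    mid_chrom[inside] <- as.character(
      GenomicRanges::seqnames(merged))[pick]
  }
  n_out <- n_hots - n_in
  if (n_out > 0) {
    # rejection-sample uniform points outside the merged footprint
    need <- which(!inside)
    got <- 0L
    while (got < n_out) {
      m <- (n_out - got) * 2L + 10L
      cs <- sample(chroms, m, replace = TRUE,
                   prob = as.numeric(genome_sizes) / total)
      ps <- floor(runif(m, 0, genome_sizes[cs])) + 1
      cand <- GenomicRanges::GRanges(cs, IRanges::IRanges(ps, width = 1))
      ok <- !IRanges::overlapsAny(cand, merged)
      take <- min(sum(ok), n_out - got)
      if (take > 0) {
        sel <- which(ok)[seq_len(take)]
        rows <- need[got + seq_len(take)]
        mids[rows] <- ps[sel]
        mid_chrom[rows] <- cs[sel]
        got <- got + take
      }
    }
  }
  hots <- if (n_hots > 0) {
    starts <- pmax(1, mids - floor(hot_width / 2))
    ends <- pmin(genome_sizes[mid_chrom], starts + hot_width - 1)
    GenomicRanges::GRanges(mid_chrom,
                           IRanges::IRanges(start = starts, end = ends))
  } else {
    GenomicRanges::GRanges()
  }
  S4Vectors::mcols(hots)$role <- if (n_hots > 0) "HOT" else character(0)

  realized <- if (n_hots > 0) {
    sum(IRanges::overlapsAny(
      GenomicRanges::resize(hots, width = 1, fix = "center"), merged))
  } else 0L
  list(hots = hots, loops = loops,
       truth = list(p_null = p_null, enrichment_rho = enrichment_rho,
                    n_inside_drawn = n_in, realized_overlap = realized,
                    seed = seed))
}
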