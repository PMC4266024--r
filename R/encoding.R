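#' Binary input patterns
#'
#' A pattern is a binary (0/1) square matrix; each pixel drives one source
#' neuron (row-major flattening), black pixels (1) at \code{f_black} Hz.
#'
#' @param pixels binary matrix.
#' @param id optional identifier.
#' @return an object of class \code{snn_pattern}.
#' @export
snn_pattern <- function(pixels, id = NULL) {
  stopifnot(is.matrix(pixels), all(pixels %in% c(0, 1)))
  structure(list(id = id, pixels = pixels), class = "snn_pattern")
}

#' @export
print.snn_pattern <- function(x, ...) {
  cat(sprintf("<snn_pattern %s: %d x %d, %d black pixels>\n",
              if (is.null(x$id)) "" else x$id, nrow(x$pixels), ncol(x$pixels),
              sum(x$pixels)))
  invisible(x)
}

#' Read and write patterns as plain-text grids or PNG images
#'
#' Text grids hold one row of \code{0}/\code{1} characters per line; a
#' \code{.png} path writes/reads a lossless image (black pixels = 1).
#'
#' @param pattern an \code{\link{snn_pattern}}.
#' @param path file path; \code{.png} selects the image format.
#' @return \code{read_pattern} returns an \code{snn_pattern}.
#' @export
write_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "snn_pattern"))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(1 - pattern$pixels, path)
  } else {
    writeLines(apply(pattern$pixels, 1, paste, collapse = ""), path)
  }
  invisible(path)
}

#' @rdname write_pattern
#' @param id identifier for the pattern read.
#' @export
read_pattern <- function(path, id = NULL) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    return(snn_pattern((img < 0.5) + 0, id = id))
  }
  rows <- strsplit(readLines(path), "")
  px <- do.call(rbind, lapply(rows, as.integer))
  snn_pattern(px, id = id)
}

# row-major flattening of pixels to the source-layer vector
flatten_pattern <- function(pattern) as.vector(t(pattern$pixels))

# K x P matrix of flattened patterns
pattern_matrix <- function(patterns, cfg) {
  stopifnot(length(patterns) >= 1)
  m <- vapply(patterns, flatten_pattern, numeric(cfg$K))
  if (nrow(m) != cfg$K) stop("pattern size does not match cfg$K")
  m
}

#' Generate synthetic stripe/block/diagonal/disc patterns
#'
#' Builds a set of distinct binary images from the motif vocabulary of the
#' study's flag-like training set: horizontal and vertical bars, corner or
#' centre blocks, diagonal bands and discs, composed two or three motifs at
#' a time.  Pairwise overlap (Jaccard index of black pixels) is kept below
#' \code{max_overlap} by rejection.
#'
#' @param count number of patterns.
#' @param size image side length (>= 5).
#' @param max_overlap maximal pairwise Jaccard overlap allowed.
#' @param motifs character subset of
#'   \code{c("hbar", "vbar", "block", "diag", "disc")}.
#' @param seed optional RNG seed; the same seed reproduces the same set.
#' @return a list of \code{\link{snn_pattern}} objects.
#' @examples
#' pats <- flag_patterns(4, 15, seed = 1)
#' @export
flag_patterns <- function(count, size, max_overlap = 0.6,
                          motifs = c("hbar", "vbar", "block", "diag", "disc"),
                          seed = NULL) {
  stopifnot(size >= 5, count >= 1)
  motifs <- match.arg(motifs, several.ok = TRUE)
  with_seed(seed, {
    draw_motif <- function(kind) {
      px <- matrix(0L, size, size)
      thick <- max(2L, round(size / 5))
      switch(kind,
        hbar = { r <- sample.int(size - thick + 1, 1)
                 px[r:(r + thick - 1), ] <- 1L },
        vbar = { c0 <- sample.int(size - thick + 1, 1)
                 px[, c0:(c0 + thick - 1)] <- 1L },
        block = { h <- sample(seq(round(size / 3), round(2 * size / 3)), 1)
                  w <- sample(seq(round(size / 3), round(2 * size / 3)), 1)
                  r <- sample.int(size - h + 1, 1); c0 <- sample.int(size - w + 1, 1)
                  px[r:(r + h - 1), c0:(c0 + w - 1)] <- 1L },
        diag = { off <- sample(seq(-round(size / 3), round(size / 3)), 1)
                 anti <- runif(1) < 0.5
                 for (i in seq_len(size)) for (j in seq_len(size)) {
                   d <- if (anti) i + j - size - 1 - off else i - j - off
                   if (abs(d) < thick / 2 + 0.5) px[i, j] <- 1L
                 } },
        disc = { cx <- sample(seq(round(size / 3), round(2 * size / 3)), 2, replace = TRUE)
                 rad <- sample(seq(round(size / 5), round(size / 3)), 1)
                 for (i in seq_len(size)) for (j in seq_len(size))
                   if ((i - cx[1])^2 + (j - cx[2])^2 <= rad^2) px[i, j] <- 1L })
      px
    }
    jac <- function(a, b) {
      u <- sum(a | b)
      if (u == 0) 0 else sum(a & b) / u
    }
    out <- list()
    tries <- 0
    while (length(out) < count && tries < 400 * count) {
      tries <- tries + 1
      n_m <- sample(2:3, 1)
      px <- matrix(0L, size, size)
      for (k in sample(motifs, n_m, replace = TRUE)) px <- pmax(px, draw_motif(k))
      frac <- mean(px)
      if (frac < 0.1 || frac > 0.6) next
      if (length(out) && any(vapply(out, function(p) jac(p$pixels, px), 0) > max_overlap))
        next
      out[[length(out) + 1]] <- snn_pattern(px, id = length(out) + 1)
    }
    if (length(out) < count)
      stop("could not generate ", count, " sufficiently distinct patterns")
    out
  })
}

#' Encode a pattern as Poisson spike trains
#'
#' Source neurons of black pixels spike as Bernoulli(\code{f_black * dt})
#' per step; a random fraction \code{noise_fraction} of white-pixel neurons
#' (redrawn per presentation) spikes at \code{f_noise}; remaining white
#' pixels stay silent.
#'
#' @param pattern an \code{\link{snn_pattern}}.
#' @param duration_ms presentation length in ms (> 0).
#' @param cfg an \code{\link{snn_config}}.
#' @param seed optional RNG seed.
#' @return a data frame with columns \code{layer} (\code{"source"}),
#'   \code{neuron_id}, \code{time_ms} - the spike record of the source layer.
#' @export
encode_poisson <- function(pattern, duration_ms, cfg, seed = NULL) {
  stopifnot(duration_ms > 0)
  pb <- cfg$f_black * cfg$dt / 1000
  pn <- cfg$f_noise * cfg$dt / 1000
  if (pb > 1 || pn > 1) stop("f * dt exceeds 1")
  with_seed(seed, {
    px <- flatten_pattern(pattern)
    if (length(px) != cfg$K) stop("pattern size does not match cfg$K")
    p <- ifelse(px > 0.5, pb, ifelse(runif(cfg$K) < cfg$noise_fraction, pn, 0))
    steps <- ceiling(duration_ms / cfg$dt)
    active <- which(p > 0)
    sp <- lapply(active, function(k) which(runif(steps) < p[k]) * cfg$dt)
    n <- lengths(sp)
    data.frame(layer = rep("source", sum(n)),
               neuron_id = rep(active, n),
               time_ms = unlist(sp))
  })
}

#' Random training schedule of exponential-duration presentations
#'
#' Patterns are drawn i.i.d. uniformly; durations are i.i.d. exponential
#' with mean \code{cfg$mean_pattern_duration} ms, rounded up to at least one
#' time step; segments are concatenated until \code{total_ms} is covered.
#'
#' @param patterns list of \code{\link{snn_pattern}} objects.
#' @param total_ms total schedule length to cover (ms).
#' @param cfg an \code{\link{snn_config}}.
#' @param seed optional RNG seed.
#' @return a schedule data frame: \code{pattern_id, onset_ms, duration_ms}.
#' @export
training_schedule <- function(patterns, total_ms, cfg, seed = NULL) {
  P <- length(patterns)
  stopifnot(P >= 1, total_ms > 0)
  with_seed(seed, {
    n_guess <- ceiling(1.3 * total_ms / cfg$mean_pattern_duration) + 20
    ids <- integer(0); durs <- numeric(0); covered <- 0
    while (covered < total_ms) {
      d <- pmax(ceiling(stats::rexp(n_guess, 1 / cfg$mean_pattern_duration) / cfg$dt) * cfg$dt,
                cfg$dt)
      ids <- c(ids, sample.int(P, n_guess, replace = TRUE))
      durs <- c(durs, d)
      covered <- sum(durs)
    }
    keep <- which(cumsum(durs) - durs < total_ms)
    data.frame(pattern_id = ids[keep],
               onset_ms = cumsum(durs[keep]) - durs[keep],
               duration_ms = durs[keep])
  })
}

#' Fixed test schedule for discriminability probes
#'
#' Every pattern is presented \code{J} times for exactly \code{d_s} seconds
#' each.  The default ordering cycles through the patterns in a fixed
#' sequence repeated \code{J} times; \code{order = "random"} shuffles all
#' \code{J * P} segments.
#'
#' @param patterns list of \code{\link{snn_pattern}} objects.
#' @param d_s presentation duration in seconds (> 0).
#' @param J repeats per pattern (>= 1).
#' @param cfg an \code{\link{snn_config}}.
#' @param order \code{"fixed"} (default) or \code{"random"}.
#' @param seed optional RNG seed (used for random order).
#' @return a schedule data frame: \code{pattern_id, onset_ms, duration_ms}.
#' @export
test_schedule <- function(patterns, d_s = cfg$d_test, J = cfg$J, cfg,
                          order = c("fixed", "random"), seed = NULL) {
  order <- match.arg(order)
  P <- length(patterns)
  stopifnot(P >= 1, J >= 1)
  if (d_s <= 0) stop("test presentation duration must be positive")
  ids <- rep(seq_len(P), times = J)
  if (order == "random") ids <- with_seed(seed, sample(ids))
  d_ms <- ceiling(d_s * 1000 / cfg$dt) * cfg$dt
  data.frame(pattern_id = ids,
             onset_ms = (seq_along(ids) - 1) * d_ms,
             duration_ms = d_ms)
}

#' Read and write schedules as CSV
#'
#' Columns \code{pattern_id, onset_ms, duration_ms}.
#'
#' @param schedule a schedule data frame.
#' @param path file path.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(schedule, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  utils::read.csv(path)
}

#' Write a spike record as CSV
#'
#' Columns \code{layer, neuron_id, time_ms}.
#'
#' @param spikes a spike-record data frame (see \code{\link{run_network}}).
#' @param path file path.
#' @export
write_spikes <- function(spikes, path) {
  utils::write.csv(spikes, path, row.names = FALSE)
  invisible(path)
}
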