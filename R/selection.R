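# Antigen-selection strength on replacement vs silent mutations.
#
# A focused Bayesian estimate in the spirit of BASELINe: observed replacement
# (R) and silent (S) counts in a region are compared with the expected
# replacement fraction pi0 under a targeting model. With a flat Beta(1, 1)
# prior on the true replacement fraction theta, the posterior is
# Beta(R + 1, S + 1); selection strength is the log odds ratio
# Sigma = log[(theta / (1 - theta)) / (pi0 / (1 - pi0))], with its posterior
# density evaluated on a fixed Sigma grid. Counts are pooled across the
# sequences of a group (pooled-counts aggregation, not per-sequence
# convolution).

#' Classify single-nucleotide mutations as replacement, silent or stop
#'
#' Translates the affected codon before and after each mutation.
#' Substitutions creating a stop codon (or hitting a reference stop) are
#' classed `stop` and by default excluded from R:S analyses.
#'
#' @param mutations Mutation tibble (`position`, `from`, `to`; positions
#'   1-based on `reference_nt`).
#' @param reference_nt Reference nucleotide string.
#' @param reading_frame_offset 0-based offset of the first codon position
#'   (default 0: translation starts at position 1).
#' @return `mutations` with an added `rs_class` column in
#'   `c("R", "S", "stop")`; NA for positions without a complete codon.
#' @export
classify_r_s <- function(mutations, reference_nt, reading_frame_offset = 0L) {
  s <- nt_chars(reference_nt)
  L <- length(s)
  gc <- Biostrings::GENETIC_CODE
  cls <- rep(NA_character_, nrow(mutations))
  for (i in seq_len(nrow(mutations))) {
    pos <- mutations$position[i]
    idx0 <- pos - 1L - reading_frame_offset
    if (idx0 < 0) next
    start <- reading_frame_offset + 3L * (idx0 %/% 3L) + 1L
    if (start + 2L > L) next
    codon <- s[start:(start + 2L)]
    if (any(!codon %in% c("A", "C", "G", "T"))) next
    mutated <- codon
    mutated[pos - start + 1L] <- mutations$to[i]
    if (!mutations$to[i] %in% c("A", "C", "G", "T")) next
    aa0 <- gc[[paste(codon, collapse = "")]]
    aa1 <- gc[[paste(mutated, collapse = "")]]
    cls[i] <- if (aa0 == "*" || aa1 == "*") "stop" else if (aa0 == aa1) "S" else "R"
  }
  mutations$rs_class <- cls
  mutations
}

#' Position weights of a targeting model
#'
#' The uniform model weights every position equally. A motif-weighted model
#' is a named numeric vector of k-mer weights (odd k); each position receives
#' the weight of its centered k-mer (1 when the k-mer is absent from the
#' table or the window is incomplete), so published SHM targeting tables can
#' be dropped in.
#'
#' @param reference_nt Reference sequence.
#' @param model `NULL` for uniform, or a named numeric k-mer weight vector.
#' @return Non-negative numeric vector over positions.
#' @export
targeting_weights <- function(reference_nt, model = NULL) {
  L <- nchar(reference_nt)
  if (is.null(model)) return(rep(1, L))
  stopifnot(is.numeric(model), !is.null(names(model)), all(model >= 0))
  k <- unique(nchar(names(model)))
  stopifnot(length(k) == 1, k %% 2 == 1)
  half <- (k - 1L) / 2L
  s <- nt_chars(reference_nt)
  w <- rep(1, L)
  for (i in seq_len(L)) {
    if (i - half < 1 || i + half > L) next
    kmer <- paste(s[(i - half):(i + half)], collapse = "")
    if (kmer %in% names(model)) w[i] <- model[[kmer]]
  }
  w
}

#' Expected replacement fraction under a targeting model
#'
#' Enumerates every (position, substitution) pair within each region
#' interval, classifies it as R, S or stop, and computes
#' `pi0 = sum of weights of R-producing pairs / sum of weights of R- and
#' S-producing pairs`. Stop-producing substitutions are excluded from both
#' sums by default (`stop_policy = "exclude"`) or counted as replacements
#' (`"as_R"`).
#'
#' @param reference_nt Reference sequence.
#' @param regions Tibble with columns `start`, `end` (1-based closed) and
#'   `type` (`"CDR"` or `"FR"`).
#' @param model Targeting model (see [targeting_weights()]).
#' @param reading_frame_offset 0-based reading-frame offset.
#' @param stop_policy `"exclude"` or `"as_R"`.
#' @return Tibble `region_type`, `pi0`, `w_r`, `w_s`.
#' @export
expected_r_fraction <- function(reference_nt, regions, model = NULL,
                                reading_frame_offset = 0L,
                                stop_policy = c("exclude", "as_R")) {
  stop_policy <- match.arg(stop_policy)
  w <- targeting_weights(reference_nt, model)
  s <- nt_chars(reference_nt)
  bases <- c("A", "C", "G", "T")
  out <- lapply(unique(regions$type), function(ty) {
    pos <- unlist(lapply(which(regions$type == ty), function(r) {
      seq.int(regions$start[r], regions$end[r])
    }))
    muts <- tibble(
      position = rep(pos, each = 3L),
      from = rep(s[pos], each = 3L)
    )
    muts$to <- unlist(lapply(s[pos], function(b) setdiff(bases, b)))
    muts <- muts[muts$from %in% bases, , drop = FALSE]
    muts <- classify_r_s(muts, reference_nt, reading_frame_offset)
    muts <- muts[!is.na(muts$rs_class), , drop = FALSE]
    if (stop_policy == "as_R") {
      muts$rs_class[muts$rs_class == "stop"] <- "R"
    } else {
      muts <- muts[muts$rs_class != "stop", , drop = FALSE]
    }
    wr <- sum(w[muts$position[muts$rs_class == "R"]])
    ws <- sum(w[muts$position[muts$rs_class == "S"]])
    tibble(region_type = ty, pi0 = wr / (wr + ws), w_r = wr, w_s = ws)
  })
  bind_rows(out)
}

#' Posterior selection strength from pooled R and S counts
#'
#' @param r,s Observed replacement and silent counts (pooled over the
#'   group's sequences); `r + s >= 1`.
#' @param pi0 Expected replacement fraction in (0, 1), from
#'   [expected_r_fraction()].
#' @param sigma_grid Grid over which the posterior density of Sigma is
#'   evaluated.
#' @return Object of class `selection_result`: `sigma` (grid), `density`
#'   (integrates to 1 on the grid), `mode`, `ci` (equal-tailed 95% credible
#'   interval), and the inputs.
#' @export
selection_strength <- function(r, s, pi0, sigma_grid = seq(-10, 10, by = 0.01)) {
  if (r + s < 1) stop("need at least one classified mutation")
  if (pi0 <= 0 || pi0 >= 1) stop("degenerate expected replacement fraction")
  theta <- plogis(sigma_grid + qlogis(pi0))
  # Beta(r+1, s+1) posterior on theta; Jacobian dtheta/dsigma = theta(1-theta)
  logf <- r * log(theta) + s * log1p(-theta) + log(theta) + log1p(-theta)
  logf <- logf - max(logf)
  f <- exp(logf)
  z <- trapz_weights(sigma_grid)
  f <- f / sum(f * z)
  # trapezoid CDF (cdf[i] = integral up to sigma_grid[i])
  dx <- diff(sigma_grid)
  cdf <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * dx))
  ci <- c(grid_quantile(sigma_grid, cdf, 0.025),
          grid_quantile(sigma_grid, cdf, 0.975))
  # the sigma-space posterior is Beta(r+1, s+1) in theta times the Jacobian,
  # i.e. proportional to theta^(r+1) (1-theta)^(s+1); its mode is closed-form
  mode <- qlogis((r + 1) / (r + s + 2)) - qlogis(pi0)
  structure(list(
    sigma = sigma_grid, density = f,
    mode = mode,
    ci = ci, r = r, s = s, pi0 = pi0
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Selection strength: mode %.3f, 95%% CI [%.3f, %.3f] (R=%d, S=%d, pi0=%.3f)\n",
              x$mode, x$ci[1], x$ci[2], x$r, x$s, x$pi0))
  invisible(x)
}

#' @noRd
trapz_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  w[1] <- (x[2] - x[1]) / 2
  w[n] <- (x[n] - x[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  w
}

#' @noRd
grid_quantile <- function(x, cdf, p) {
  i <- which(cdf >= p)[1]
  if (is.na(i) || i == 1) return(x[1])
  x[i - 1] + (x[i] - x[i - 1]) * (p - cdf[i - 1]) / (cdf[i] - cdf[i - 1])
}

#' Compare selection strength between two groups
#'
#' Two-sided comparison via the posterior probability that one group's Sigma
#' exceeds the other's, computed by exact summation over the two grid
#' densities: `p = 2 * min(P(S1 > S2), P(S1 < S2))`, capped at 1.
#'
#' @param a,b `selection_result` objects on identical grids.
#' @return List: `p_greater` (= P(Sigma_a > Sigma_b)), `p_value`.
#' @export
compare_selection <- function(a, b) {
  stopifnot(identical(a$sigma, b$sigma))
  z <- trapz_weights(a$sigma)
  dx <- diff(b$sigma)
  cdf_b <- c(0, cumsum((b$density[-1] + b$density[-length(b$density)]) / 2 * dx))
  # P(Sigma_a > Sigma_b) = sum_i f_a(x_i) w_i F_b(x_i) (grid approximation)
  p_gt <- sum(a$density * z * cdf_b)
  p <- min(1, 2 * min(p_gt, 1 - p_gt))
  list(p_greater = p_gt, p_value = p)
}

#' Pooled R/S selection analysis for a set of sequences
#'
#' Calls mutations of each sequence against the reference, classifies R/S,
#' pools counts by region type (CDR vs FR), and estimates selection strength
#' per region.
#'
#' @param sequences Character vector of aligned sequences (one per unique
#'   subclone).
#' @param reference_nt Reference (CDC for post-CDC groups, germline for CDC
#'   groups).
#' @param regions Region tibble (`start`, `end`, `type`).
#' @param model Targeting model.
#' @param reading_frame_offset 0-based reading-frame offset.
#' @return Named list of `selection_result`s (one per region type present);
#'   regions with zero classified mutations are omitted.
#' @export
selection_by_region <- function(sequences, reference_nt, regions, model = NULL,
                                reading_frame_offset = 0L) {
  pi0 <- expected_r_fraction(reference_nt, regions, model, reading_frame_offset)
  muts <- bind_rows(lapply(sequences, call_mutations, cdc_nt = reference_nt))
  if (nrow(muts) == 0) return(list())
  muts <- classify_r_s(muts, reference_nt, reading_frame_offset)
  muts$region <- region_of_position(muts$position, regions)
  out <- list()
  for (ty in unique(regions$type)) {
    sub <- muts[!is.na(muts$region) & muts$region == ty &
                  muts$rs_class %in% c("R", "S"), , drop = FALSE]
    if (nrow(sub) == 0) next
    out[[ty]] <- selection_strength(sum(sub$rs_class == "R"),
                                    sum(sub$rs_class == "S"),
                                    pi0$pi0[pi0$region_type == ty])
  }
  out
}

#' Region type of each position
#' @param position Integer positions.
#' @param regions Region tibble (`start`, `end`, `type`).
#' @return Character vector of region types (NA outside all intervals).
#' @export
region_of_position <- function(position, regions) {
  out <- rep(NA_character_, length(position))
  for (r in seq_len(nrow(regions))) {
    inside <- position >= regions$start[r] & position <= regions$end[r]
    out[inside] <- regions$type[r]
  }
  out
}
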