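# Independent reference implementations used to validate the package against
# first principles. These deliberately share no code with R/: stall windows
# are enumerated exhaustively, statistics recomputed from textbook formulas.

# Exhaustive run/pause segmenter. Enumerates every window of frames, keeps
# windows in which every per-frame movement is within tolerance and that span
# at least `pause_min` frames, reduces them to maximal stall windows, then
# walks the complementary stretches step by step splitting at direction
# reversals. Quadratic and slow; only for short tracks.
oracle_segment <- function(positions, frames, rules, dt) {
  n <- length(positions)
  tol <- rules$same_position_tol
  pmin_f <- rules$pause_min_frames

  valid <- function(i, j) {
    if (j - i + 1L < pmin_f) return(FALSE)
    for (k in i:(j - 1L)) {
      if (abs(positions[k + 1L] - positions[k]) > tol) return(FALSE)
    }
    TRUE
  }
  stalls <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (!valid(i, j)) next
    left_ext <- i > 1L && valid(i - 1L, j)
    right_ext <- j < n && valid(i, j + 1L)
    if (!left_ext && !right_ext) stalls[[length(stalls) + 1L]] <- c(i, j)
  }
  stalls <- unique(stalls)
  if (length(stalls))
    stalls <- stalls[order(vapply(stalls, `[`, numeric(1), 1))]

  pauses <- data.frame(
    start_frame = vapply(stalls, function(s) frames[s[1]], numeric(1)),
    end_frame = vapply(stalls, function(s) frames[s[2]], numeric(1)),
    duration_s = vapply(stalls, function(s) (s[2] - s[1]) * dt, numeric(1)))

  # complementary stretches, each extended one frame into adjacent stalls
  cuts <- c(0L, unlist(stalls), n + 1L)
  m <- matrix(cuts, ncol = 2, byrow = TRUE)  # (prev_end, next_start) pairs
  runs <- list()
  for (r in seq_len(nrow(m))) {
    a <- max(1L, m[r, 1])            # last frame of previous stall (or 1)
    b <- min(n, m[r, 2])             # first frame of next stall (or n)
    if (b - a < 1L) next
    # walk steps, splitting at reversals; sub-tolerance steps are
    # directionless, and the cut between opposite-signed stretches sits at the
    # extremal position inside the ambiguous (sub-tolerance) window
    emit <- function(s, e) {
      disp <- abs(positions[e] - positions[s])
      if (disp < rules$run_threshold) return(NULL)
      moving <- 0L
      for (k in s:(e - 1L))
        if (abs(positions[k + 1L] - positions[k]) > tol) moving <- moving + 1L
      if (moving == 0L) return(NULL)
      data.frame(direction = if (positions[e] > positions[s]) "anterograde"
                             else "retrograde",
                 start_frame = frames[s], end_frame = frames[e],
                 displacement_um = disp, duration_s = moving * dt,
                 mean_speed_um_s = disp / (moving * dt))
    }
    seg_start <- a; sgn <- 0L; last_big_end <- NA_integer_
    for (k in a:(b - 1L)) {
      d <- positions[k + 1L] - positions[k]
      s_k <- if (abs(d) <= tol) 0L else as.integer(sign(d))
      if (s_k == 0L) next
      if (sgn == 0L) {
        sgn <- s_k
      } else if (s_k != sgn) {
        window <- last_big_end:k
        cut <- window[if (sgn > 0L) which.max(positions[window])
                      else which.min(positions[window])]
        runs[[length(runs) + 1L]] <- emit(seg_start, cut)
        seg_start <- cut; sgn <- s_k
      }
      last_big_end <- k + 1L
    }
    runs[[length(runs) + 1L]] <- emit(seg_start, b)
  }
  runs <- Filter(Negate(is.null), runs)
  runs <- if (length(runs)) do.call(rbind, runs) else
    data.frame(direction = character(0), start_frame = integer(0),
               end_frame = integer(0), displacement_um = numeric(0),
               duration_s = numeric(0), mean_speed_um_s = numeric(0))
  list(runs = runs, pauses = pauses)
}

# pooled-variance two-sample t statistic, textbook formula
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# one-way ANOVA F from the sum-of-squares decomposition
oracle_anova_f <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  ss_between <- sum(tapply(values, groups, function(v)
    length(v) * (mean(v) - grand)^2))
  ss_within <- sum(tapply(values, groups, function(v)
    sum((v - mean(v))^2)))
  df_b <- nlevels(groups) - 1
  df_w <- length(values) - nlevels(groups)
  (ss_between / df_b) / (ss_within / df_w)
}

# Tukey HSD adjusted p for one pair, from the studentized range distribution
oracle_tukey_p <- function(values, groups, g1, g2) {
  groups <- factor(groups)
  mse <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2))) /
    (length(values) - nlevels(groups))
  n1 <- sum(groups == g1); n2 <- sum(groups == g2)
  se <- sqrt(mse / 2 * (1 / n1 + 1 / n2))
  q <- abs(mean(values[groups == g1]) - mean(values[groups == g2])) / se
  stats::ptukey(q, nlevels(groups), length(values) - nlevels(groups),
                lower.tail = FALSE)
}

# maximum-cardinality, minimum-total-distance matching by exhaustive
# recursion over admissible pairs (only workable when candidates are few)
oracle_optimal_matching <- function(a, b, max_distance) {
  d <- sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2)
  cand <- which(d <= max_distance, arr.ind = TRUE)
  if (nrow(cand) == 0) return(list(n = 0L, total = 0))
  best <- list(n = 0L, total = Inf)
  recurse <- function(k, used_a, used_b, n, total) {
    if (k > nrow(cand)) {
      if (n > best$n || (n == best$n && total < best$total))
        best <<- list(n = n, total = total)
      return(invisible())
    }
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      recurse(k + 1L, used_a, used_b, n + 1L, total + d[i, j])
      used_a[i] <- FALSE; used_b[j] <- FALSE
    }
    recurse(k + 1L, used_a, used_b, n, total)
  }
  recurse(1L, logical(nrow(a)), logical(nrow(b)), 0L, 0)
  best
}
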