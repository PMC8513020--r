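# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small cohort with the default effect ladder: 2 participants x 5 bouts x 30 s
tiny_cohort <- function() {
  cached("tiny_cohort", function() {
    simulate_cohort(sim_config(n_participants = 2, bout_duration = 30,
                               seed = 101L))
  })
}

tiny_dataset <- function() {
  cached("tiny_dataset", function() {
    cohort <- tiny_cohort()
    windows <- segment_cohort(cohort)
    cohort |>
      extract_features(windows) |>
      normalize_features() |>
      assemble_dataset(cohort$labels)
  })
}

# cohort with weak effects spread over several modalities, so no single
# feature separates the classes on its own
spread_dataset <- function() {
  cached("spread_dataset", function() {
    cfg <- sim_config(n_participants = 3, bout_duration = 40,
                      effect_cycle_time = 0.02, effect_emg_rms = -0.03,
                      effect_foot_accel = 0.02, effect_torso = 0.02,
                      seed = 202L)
    cohort <- simulate_cohort(cfg)
    windows <- segment_cohort(cohort)
    cohort |>
      extract_features(windows) |>
      normalize_features() |>
      assemble_dataset(cohort$labels)
  })
}

# match detected events to ground truth within a sample tolerance
event_recovery <- function(cohort, events, tol_samples = 3) {
  fs <- cohort$config$fs_imu
  tol <- tol_samples / fs
  purrr::pmap_dfr(cohort$truth[, c("participant", "bout")],
                  function(participant, bout) {
    truth <- cohort$truth$heel_strikes[[
      which(cohort$truth$participant == participant &
              cohort$truth$bout == bout)]]
    det <- events$time_s[events$participant == participant &
                           events$bout == bout]
    tibble::tibble(
      participant = participant, bout = bout,
      n_true = length(truth),
      n_hit = sum(vapply(truth, function(t) any(abs(det - t) <= tol),
                         logical(1))),
      n_false = sum(vapply(det, function(t) !any(abs(truth - t) <= tol),
                           logical(1)))
    )
  })
}

# --- independent brute-force oracles for the window statistics ------------

oracle_stats <- function(x, fs) {
  n <- length(x)
  m <- sum(x) / n
  v <- sum((x - m)^2) / n
  # histogram entropy via explicit per-bin counting
  ent <- 0; kur <- 0
  if (v > 0) {
    lo <- min(x); hi <- max(x); w <- (hi - lo) / 16
    counts <- vapply(seq_len(16), function(b) {
      if (b < 16) sum(x >= lo + (b - 1) * w & x < lo + b * w)
      else sum(x >= lo + 15 * w & x <= hi)
    }, numeric(1))
    p <- counts[counts > 0] / n
    ent <- -sum(p * log(p))
    kur <- (sum((x - m)^4) / n) / v^2 - 3
  }
  # brute-force DFT over non-DC bins
  ks <- seq_len(floor(n / 2))
  mags <- vapply(ks, function(k) {
    re <- sum(x * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(x * sin(-2 * pi * k * (0:(n - 1)) / n))
    sqrt(re^2 + im^2)
  }, numeric(1))
  freqs <- ks * fs / n
  if (sum(mags^2) > 0) {
    maxfreq <- freqs[which.max(mags)]
    pp <- mags^2 / sum(mags^2)
    mu <- sum(pp * freqs)
    stdfreq <- sqrt(sum(pp * (freqs - mu)^2))
  } else {
    maxfreq <- 0; stdfreq <- 0
  }
  c(mean = m, std = sqrt(v), max = max(x), var = v,
    median = stats::median(x), energy = sum(x^2) / n, entropy = ent,
    kurtosis = kur, maxfreq = maxfreq, stdfreq = stdfreq)
}

# recount all metrics directly from raw label pairs (independent of the
# confusion-matrix path)
oracle_metrics <- function(truth, pred, classes) {
  acc <- mean(truth == pred)
  per <- lapply(classes, function(c) {
    tp <- sum(truth == c & pred == c)
    fp <- sum(truth != c & pred == c)
    fn <- sum(truth == c & pred != c)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(p = p, r = r, f = f, tp = tp, fp = fp, fn = fn)
  })
  mat <- do.call(rbind, per)
  list(accuracy = acc,
       macro_precision = mean(mat[, "p"]),
       macro_recall = mean(mat[, "r"]),
       macro_f1 = mean(mat[, "f"]),
       pooled_precision = sum(mat[, "tp"]) / (sum(mat[, "tp"]) + sum(mat[, "fp"])),
       pooled_recall = sum(mat[, "tp"]) / (sum(mat[, "tp"]) + sum(mat[, "fn"])))
}
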