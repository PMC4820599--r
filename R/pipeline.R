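# Orchestration of the factorial Monte-Carlo study: enumerate
# configurations, run simulate -> invert -> map -> score over the
# regularization grid, and aggregate optima.

#' Study configuration
#'
#' Defaults describe the desk-scale study: a 642-vertex folded spherical
#' source space inside a 9 cm conductor, 100 radial magnetometers on a
#' 12 cm shell, 50 random location pairs crossed with patch areas
#' \{0, 2, 4\} cm^2, couplings \{0.2, 0.4\} and SNRs \{0, -20\} dB, scored
#' over the 7-value decade grid `1e-11 ... 1e-5`.  The full-scale design
#' (600 pairs, areas \{0,2,4,8\}, couplings \{0.1,0.2,0.4\}, SNRs
#' \{0,-20,-40\}) is expressible by overriding the factor lists.
#'
#' `lambda_scale` maps the nominal decade grid onto the solved system
#' (`A = L L' + nominal * lambda_scale * Q`): it is the lead-field
#' normalization constant of the synthetic setup, fixed once by range
#' inspection on a pilot subset so that the grid brackets both optima and
#' the L-curve corner (the same procedure used to pick the original range).
#'
#' @param n_location_pairs number of random source-pair locations.
#' @param patch_areas patch areas in cm^2 (0 = point-like).
#' @param couplings target band coherences.
#' @param snr_levels sensor SNRs in dB.
#' @param grid_exponents `c(low, high)` decade exponents of the nominal
#'   regularization grid.
#' @param lambda_scale nominal-to-effective regularization conversion.
#' @param subdivision_level icosphere subdivision of the source space.
#' @param source_radius source shell radius (m).
#' @param wrinkle_amplitude,wrinkle_order folding of the cortical stand-in
#'   surface (see [build_cortical_source_space()]).
#' @param conductor_radius conductor sphere radius (m).
#' @param n_sensors,sensor_shell,coverage_fraction sensor cap layout.
#' @param sensor_type `"magnetometer"` or `"axial_gradiometer"`.
#' @param gradiometer_baseline baseline (m) for gradiometer mode.
#' @param oscillator an [oscillator_spec()].
#' @param welch a [welch_params()].
#' @param band scored frequency band (Hz).
#' @param amplitude dipole moment per active vertex (A*m).
#' @param coherence_tolerance,max_coupling_iterations coupling-loop control.
#' @param min_seed_separation minimum Euclidean distance between the two
#'   seeds of a pair (m).
#' @param min_gain_fraction location pairs are drawn from vertices whose
#'   lead-field column norm is at least this fraction of the median (a
#'   perfectly silent vertex is an artifact of the synthetic surface, not a
#'   feature of cortical sampling).
#' @param master_seed master RNG seed; every random draw in the study is
#'   derived from it deterministically.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_location_pairs = 50,
                         patch_areas = c(0, 2, 4),
                         couplings = c(0.2, 0.4),
                         snr_levels = c(0, -20),
                         grid_exponents = c(-11, -5),
                         lambda_scale = 1e8,
                         subdivision_level = 3,
                         source_radius = 0.08,
                         wrinkle_amplitude = 0.12,
                         wrinkle_order = 6,
                         conductor_radius = 0.09,
                         n_sensors = 100,
                         sensor_shell = 0.12,
                         coverage_fraction = 0.5,
                         sensor_type = "magnetometer",
                         gradiometer_baseline = 0.05,
                         oscillator = oscillator_spec(),
                         welch = welch_params(),
                         band = c(9, 14),
                         amplitude = 1,
                         coherence_tolerance = 0.02,
                         max_coupling_iterations = 2000,
                         min_seed_separation = 0.03,
                         min_gain_fraction = 0.2,
                         master_seed = 20260921) {
  stopifnot(n_location_pairs >= 1, length(patch_areas) >= 1,
            length(couplings) >= 1, length(snr_levels) >= 1,
            grid_exponents[1] <= grid_exponents[2], lambda_scale > 0)
  structure(as.list(environment()), class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf(paste0(
    "study_config: %d pairs x %d areas x %d couplings x %d SNRs = %d cells\n",
    "  grid 1e%d..1e%d (x %.3g), master seed %d\n"),
    x$n_location_pairs, length(x$patch_areas), length(x$couplings),
    length(x$snr_levels),
    x$n_location_pairs * length(x$patch_areas) * length(x$couplings) *
      length(x$snr_levels),
    x$grid_exponents[1], x$grid_exponents[2], x$lambda_scale,
    x$master_seed))
  invisible(x)
}

#' Build the study geometry (source space, sensors, lead field)
#'
#' @param cfg a [study_config()].
#' @return List with `ss`, `sa`, `lf` and `column_norms`.
#' @export
build_study_geometry <- function(cfg) {
  ss <- build_cortical_source_space(cfg$subdivision_level, cfg$source_radius,
                                    wrinkle_amplitude = cfg$wrinkle_amplitude,
                                    wrinkle_order = cfg$wrinkle_order)
  sa <- build_sensor_cap(cfg$n_sensors, cfg$sensor_shell,
                         cfg$coverage_fraction,
                         sensor_type = cfg$sensor_type,
                         baseline = cfg$gradiometer_baseline,
                         conductor_radius = cfg$conductor_radius)
  lf <- compute_lead_field(ss, sa, conductor_radius = cfg$conductor_radius)
  list(ss = ss, sa = sa, lf = lf,
       column_norms = sqrt(colSums(lf$gain^2)))
}

#' Enumerate the cells of the factorial design
#'
#' Draws `n_location_pairs` seed-vertex pairs (uniform over eligible
#' vertices, subject to the minimum separation, disjoint patches at the
#' largest requested area, and the minimum-gain rule), then crosses them
#' with every patch area, coupling and SNR level.  Pairs are drawn once and
#' reused across the other factors; per-cell child seeds are derived from
#' the master seed by counter-based mixing, so any cell is reproducible in
#' isolation.
#'
#' @param cfg a [study_config()].
#' @param geometry optional precomputed [build_study_geometry()] result.
#' @return An object of class `study_design`: `cells` (data.frame with one
#'   row per cell), `pairs` (data.frame of seed vertices) and `geometry`.
#' @export
enumerate_configs <- function(cfg, geometry = NULL) {
  if (is.null(geometry)) geometry <- build_study_geometry(cfg)
  ss <- geometry$ss
  cn <- geometry$column_norms
  eligible <- which(cn >= cfg$min_gain_fraction * stats::median(cn))
  if (length(eligible) < 2)
    stop("geometry error: fewer than 2 eligible source vertices")
  max_area <- max(cfg$patch_areas)

  pairs <- with_seed(derive_seed(cfg$master_seed, 777), {
    out <- matrix(0L, cfg$n_location_pairs, 2)
    for (p in seq_len(cfg$n_location_pairs)) {
      ok <- FALSE
      for (try in 1:200) {
        s12 <- sample(eligible, 2)
        d <- sqrt(sum((ss$vertices[s12[1], ] - ss$vertices[s12[2], ])^2))
        if (d < cfg$min_seed_separation) next
        if (max_area > 0) {
          p1 <- grow_patch(ss, s12[1], max_area)
          p2 <- grow_patch(ss, s12[2], max_area)
          if (length(intersect(p1$member_vertices, p2$member_vertices))) next
        }
        ok <- TRUE
        break
      }
      if (!ok)
        stop("geometry error: source space too small to host disjoint ",
             "patches at ", max_area, " cm^2 with the requested separation")
      out[p, ] <- s12
    }
    out
  })
  pairs_df <- data.frame(pair_id = seq_len(cfg$n_location_pairs),
                         seed_1 = pairs[, 1], seed_2 = pairs[, 2])

  cells <- expand.grid(pair_id = pairs_df$pair_id,
                       patch_area = cfg$patch_areas,
                       coupling = cfg$couplings,
                       snr_db = cfg$snr_levels,
                       KEEP.OUT.ATTRS = FALSE)
  cells$seed_1 <- pairs_df$seed_1[cells$pair_id]
  cells$seed_2 <- pairs_df$seed_2[cells$pair_id]
  ci <- match(cells$coupling, cfg$couplings)
  ai <- match(cells$patch_area, cfg$patch_areas)
  si <- match(cells$snr_db, cfg$snr_levels)
  # time-series seed shared by the cells that share (pair, coupling);
  # noise seed unique per cell
  cells$pair_seed <- mapply(function(p, c2) derive_seed(cfg$master_seed, 1000, p, c2),
                            cells$pair_id, ci)
  cells$noise_seed <- mapply(function(p, a, c2, s)
    derive_seed(cfg$master_seed, 2000, p, a, c2, s),
    cells$pair_id, ai, ci, si)
  cells$config_id <- sprintf("p%03d_a%g_c%g_s%g", cells$pair_id,
                             cells$patch_area, cells$coupling, cells$snr_db)
  structure(list(cells = cells, pairs = pairs_df, geometry = geometry,
                 config = cfg),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("study_design: %d cells (%d pairs)\n", nrow(x$cells),
              nrow(x$pairs)))
  invisible(x)
}

# Rank-based AUC (Mann-Whitney with midrank ties); equals the trapezoidal
# area of the exact-threshold ROC of roc_auc().  Used on the study's hot
# path where only the area is needed.
auc_rank <- function(values, truth_idx, excluded = integer(0)) {
  evaluable <- setdiff(seq_along(values), excluded)
  truth <- intersect(setdiff(truth_idx, excluded), evaluable)
  vals <- values[evaluable]
  is_t <- evaluable %in% truth
  n_t <- sum(is_t)
  n_f <- length(vals) - n_t
  if (n_t == 0 || n_f == 0) stop("undefined ROC after exclusion")
  r <- rank(vals)
  (sum(r[is_t]) - n_t * (n_t + 1) / 2) / (n_t * n_f)
}

# Band power and seed coherence for every vertex, from the sensor-level
# Welch segment FFTs and an inverse operator: since both the FFT and the
# inverse operator are linear, source segment spectra are W %*% (sensor
# segment spectra), which avoids materializing the source time series.
source_band_maps <- function(W, sens_fft, bins, seed_vertex) {
  nb <- length(bins)
  ns <- sens_fft$n_seg
  Fm <- matrix(sens_fft$fft[bins, , ], nb * ns, dim(sens_fft$fft)[3])
  Fsrc <- tcrossprod(Fm, W)                 # (bins*segs) x sources
  A2 <- Matrix_abs2(Fsrc)
  dim(A2) <- c(nb, ns, ncol(Fsrc))
  auto <- colMeans(aperm(A2, c(2, 1, 3)))   # bins x sources, mean over segs
  power <- colMeans(auto)                   # mean over band bins
  Fs <- Fsrc[, seed_vertex]
  Cx <- Conj(Fs) * Fsrc
  dim(Cx) <- c(nb, ns, ncol(Fsrc))
  cross <- colMeans(aperm(Cx, c(2, 1, 3)))  # bins x sources (complex)
  ps <- auto[, seed_vertex]
  ratio <- abs(cross)^2 / (auto * matrix(ps, nb, ncol(auto)))
  ratio[ratio > 1] <- 1
  coh <- colMeans(ratio)
  list(power = power, coherence = coh)
}

Matrix_abs2 <- function(z) Re(z)^2 + Im(z)^2

#' Run the factorial Monte-Carlo study
#'
#' For every cell of the design: draw the coupled pair (shared by the cells
#' with the same location pair and coupling), place it on the patches,
#' project to the sensors, add noise; then for every nominal grid weight
#' build the inverse operator, map band power and seed-based coherence, and
#' score both maps by ROC/AUC (power truth = both patches; coherence truth
#' = patch 2 with patch 1 excluded, seeded at patch 1's growth centre).
#' The L-curve corner is also selected per cell.  Fully deterministic given
#' `cfg$master_seed`.
#'
#' Cell failures are recorded and skipped; more than 10% failed cells is a
#' study-level error.
#'
#' @param cfg a [study_config()].
#' @param design optional precomputed [enumerate_configs()] result.
#' @param verbose print per-block progress to stderr.
#' @return An object of class `study_result`: `study_table` (one row per
#'   cell x weight x analysis), `optima` (overall and per-factor),
#'   `lcurve` (per-cell corner weights, nominal scale), `ttests`,
#'   `failed_cells`, `config`, `provenance`.
#' @export
run_study <- function(cfg, design = NULL, verbose = TRUE) {
  if (is.null(design)) design <- enumerate_configs(cfg)
  geom <- design$geometry
  ss <- geom$ss
  gain <- geom$lf$gain
  cells <- design$cells
  grid_nominal <- lambda_grid(cfg$grid_exponents[1], cfg$grid_exponents[2])
  grid_eff <- grid_nominal * cfg$lambda_scale
  n_src <- ncol(gain)

  # caches shared across cells
  pair_cache <- new.env(hash = TRUE)
  patch_cache <- new.env(hash = TRUE)

  rows <- vector("list", nrow(cells))
  lcurve_rows <- vector("list", nrow(cells))
  failed <- character(0)
  t_start <- Sys.time()

  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    res <- tryCatch({
      pk <- sprintf("pair_%d_%g", cell$pair_id, cell$coupling)
      pair <- pair_cache[[pk]]
      if (is.null(pair)) {
        pair <- generate_coupled_pair(
          cfg$oscillator, cell$coupling,
          tolerance = cfg$coherence_tolerance,
          max_iterations = cfg$max_coupling_iterations,
          rng_seed = cell$pair_seed, params = cfg$welch)
        pair_cache[[pk]] <- pair
      }
      gk1 <- sprintf("patch_%d_%g", cell$seed_1, cell$patch_area)
      gk2 <- sprintf("patch_%d_%g", cell$seed_2, cell$patch_area)
      patch_1 <- patch_cache[[gk1]]
      if (is.null(patch_1))
        patch_1 <- patch_cache[[gk1]] <- grow_patch(ss, cell$seed_1,
                                                    cell$patch_area)
      patch_2 <- patch_cache[[gk2]]
      if (is.null(patch_2))
        patch_2 <- patch_cache[[gk2]] <- grow_patch(ss, cell$seed_2,
                                                    cell$patch_area)
      m1 <- patch_1$member_vertices
      m2 <- patch_2$member_vertices
      if (length(intersect(m1, m2))) stop("patches overlap")

      # clean sensor data: members of a patch share one series, so the
      # projection is rank-2
      g1 <- rowSums(gain[, m1, drop = FALSE]) * cfg$amplitude
      g2 <- rowSums(gain[, m2, drop = FALSE]) * cfg$amplitude
      clean <- outer(g1, pair$series_1) + outer(g2, pair$series_2)
      nz <- add_noise_at_snr(clean, cell$snr_db, cell$noise_seed)

      sens_fft <- welch_seg_ffts(t(nz$noisy), cfg$welch)
      bins <- band_bins(sens_fft$freqs, cfg$band)

      truth_power <- union(m1, m2)
      auc_p <- auc_c <- numeric(length(grid_eff))
      for (k in seq_along(grid_eff)) {
        op <- make_inverse_operator(gain, NULL, nz$noise_cov, grid_eff[k])
        maps <- source_band_maps(op$w, sens_fft, bins, patch_1$seed_vertex)
        auc_p[k] <- auc_rank(maps$power, truth_power)
        auc_c[k] <- auc_rank(maps$coherence, m2, excluded = m1)
      }
      lc <- lcurve_select(gain, NULL, nz$noise_cov, nz$noisy, grid_eff)

      list(
        table = data.frame(
          config_id = cell$config_id, pair_id = cell$pair_id,
          snr_db = cell$snr_db, patch_area_cm2 = cell$patch_area,
          coupling = cell$coupling,
          reg_weight = rep(grid_nominal, 2),
          analysis = rep(c("power", "coherence"),
                         each = length(grid_nominal)),
          auc = c(auc_p, auc_c),
          achieved_coherence = pair$achieved_coherence,
          seed = cell$noise_seed),
        lcurve = data.frame(
          config_id = cell$config_id, snr_db = cell$snr_db,
          patch_area_cm2 = cell$patch_area, coupling = cell$coupling,
          corner_weight = lc$corner_weight / cfg$lambda_scale))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, paste0(cell$config_id, ": ", conditionMessage(res)))
    } else {
      rows[[i]] <- res$table
      lcurve_rows[[i]] <- res$lcurve
    }
    if (verbose && (i %% 50 == 0 || i == nrow(cells)))
      message(sprintf("  cell %d/%d (%.1f s elapsed)", i, nrow(cells),
                      as.numeric(difftime(Sys.time(), t_start, units = "secs"))))
  }

  if (length(failed) > nrow(cells) * 0.10)
    stop("study-level failure: ", length(failed), " of ", nrow(cells),
         " cells failed; first: ", failed[1])

  study_table <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  lcurve_table <- do.call(rbind,
                          lcurve_rows[!vapply(lcurve_rows, is.null,
                                              logical(1))])
  rownames(study_table) <- rownames(lcurve_table) <- NULL

  optima <- list(
    power = aggregate_optimal_lambda(study_table, "power"),
    coherence = aggregate_optimal_lambda(study_table, "coherence"),
    power_by_snr = aggregate_optimal_lambda(study_table, "power", "snr_db"),
    coherence_by_snr = aggregate_optimal_lambda(study_table, "coherence",
                                                "snr_db"),
    power_by_area = aggregate_optimal_lambda(study_table, "power",
                                             "patch_area_cm2"),
    coherence_by_area = aggregate_optimal_lambda(study_table, "coherence",
                                                 "patch_area_cm2"),
    power_by_coupling = aggregate_optimal_lambda(study_table, "power",
                                                 "coupling"),
    coherence_by_coupling = aggregate_optimal_lambda(study_table,
                                                     "coherence", "coupling"))
  w_pow <- optima$power$optima$optimal_weight
  w_coh <- optima$coherence$optima$optimal_weight

  # cross-application t-tests need enough non-degenerate configurations;
  # tiny studies simply omit them
  ttests <- tryCatch(study_cross_ttests(study_table, w_pow, w_coh),
                     error = function(e) NULL)
  lcurve_summary <- list(
    table = lcurve_table,
    mean_log10_weight = mean(log10(lcurve_table$corner_weight)),
    power_optimal_weight = w_pow,
    coherence_optimal_weight = w_coh)

  structure(list(study_table = study_table, optima = optima,
                 lcurve = lcurve_summary, ttests = ttests,
                 failed_cells = failed, config = cfg,
                 provenance = list(
                   package_version = tryCatch(
                     as.character(utils::packageVersion("mnecoh")),
                     error = function(e) NA_character_),
                   master_seed = cfg$master_seed,
                   n_cells = nrow(cells), n_failed = length(failed),
                   timestamp = format(Sys.time(), tz = "UTC"))),
            class = "study_result")
}

# paired t-tests between the two data-driven optima, applied to both
# analyses (the cross-application comparison of the study)
study_cross_ttests <- function(study_table, w_pow, w_coh) {
  pick <- function(analysis, w) {
    sub <- study_table[study_table$analysis == analysis &
                         study_table$reg_weight == w, ]
    sub[order(sub$config_id), c("config_id", "auc")]
  }
  out <- list()
  for (analysis in c("power", "coherence")) {
    a <- pick(analysis, if (analysis == "power") w_pow else w_coh)
    b <- pick(analysis, if (analysis == "power") w_coh else w_pow)
    stopifnot(identical(a$config_id, b$config_id))
    tt <- compare_auc_paired(a$auc, b$auc)
    out[[analysis]] <- data.frame(
      analysis = analysis,
      weight_a = if (analysis == "power") w_pow else w_coh,
      weight_b = if (analysis == "power") w_coh else w_pow,
      mean_auc_a = mean(a$auc), mean_auc_b = mean(b$auc),
      t = tt$t, df = tt$df, p = tt$p, mean_diff = tt$mean_diff)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.study_result <- function(x, ...) {
  cat("study_result\n")
  cat(sprintf("  cells: %d ok, %d failed\n",
              nrow(x$study_table) / (2 * length(unique(x$study_table$reg_weight))),
              length(x$failed_cells)))
  cat(sprintf("  optimal weight (power):     %.3g%s\n",
              x$optima$power$optima$optimal_weight,
              if (x$optima$power$optima$at_grid_edge) "  [grid edge]" else ""))
  cat(sprintf("  optimal weight (coherence): %.3g%s\n",
              x$optima$coherence$optima$optimal_weight,
              if (x$optima$coherence$optima$at_grid_edge) "  [grid edge]" else ""))
  cat(sprintf("  mean L-curve corner: 1e%.2f\n",
              x$lcurve$mean_log10_weight))
  invisible(x)
}

#' Write the aggregate study reports
#'
#' Emits CSV tables mirroring the study's figures: mean AUC by weight
#' (overall and per factor), the optimal-weight summary with grid-edge
#' flags, the paired t-tests between the two optima applied to both
#' analyses, the per-cell L-curve corners and their comparison to the
#' data-driven optima, plus the full study table and a plain-text summary.
#'
#' @param result a `study_result`.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_study_report <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0)
    stop("I/O error: cannot write to ", out_dir)
  files <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  put(result$study_table, "study_table.csv")
  overall <- rbind(
    cbind(analysis = "power", result$optima$power$mean_auc),
    cbind(analysis = "coherence", result$optima$coherence$mean_auc))
  overall$group <- NULL
  put(overall, "mean_auc_by_weight.csv")
  for (fac in c("snr", "area", "coupling")) {
    key <- c(snr = "by_snr", area = "by_area", coupling = "by_coupling")[fac]
    tab <- rbind(
      cbind(analysis = "power",
            result$optima[[paste0("power_", key)]]$mean_auc),
      cbind(analysis = "coherence",
            result$optima[[paste0("coherence_", key)]]$mean_auc))
    put(tab, paste0("mean_auc_", key, ".csv"))
  }
  opt <- do.call(rbind, lapply(names(result$optima), function(nm) {
    o <- result$optima[[nm]]$optima
    o$group <- NULL
    cbind(aggregate = nm, factor_level = apply(
      o[, setdiff(names(o), c("aggregate", "optimal_weight", "mean_auc",
                              "tie", "at_grid_edge")), drop = FALSE],
      1, paste, collapse = "/"),
      o[, c("optimal_weight", "mean_auc", "tie", "at_grid_edge")])
  }))
  put(opt, "optimal_weights.csv")
  if (!is.null(result$ttests)) put(result$ttests, "ttests_optima.csv")
  put(result$lcurve$table, "lcurve_corners.csv")
  put(data.frame(
    mean_log10_corner = result$lcurve$mean_log10_weight,
    power_optimal_weight = result$lcurve$power_optimal_weight,
    coherence_optimal_weight = result$lcurve$coherence_optimal_weight,
    decades_below_power = log10(result$lcurve$power_optimal_weight) -
      result$lcurve$mean_log10_weight,
    decades_below_coherence = log10(result$lcurve$coherence_optimal_weight) -
      result$lcurve$mean_log10_weight),
    "lcurve_summary.csv")

  summary_path <- file.path(out_dir, "summary.txt")
  con <- file(summary_path, "w")
  sink(con)
  print(result$config)
  print(result)
  if (!is.null(result$ttests)) {
    cat("\nPaired t-tests (optimum of one analysis applied to the other):\n")
    print(result$ttests)
  }
  sink()
  close(con)
  files <- c(files, summary_path)
  invisible(files)
}
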