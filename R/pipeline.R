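#' Run configuration
#'
#' All tunable stage parameters of the synthetic-dimer analysis pipeline
#' with their defaults, overridable individually; the resolved
#' configuration is written next to the outputs of every run and
#' round-trips losslessly through YAML.
#'
#' @param out_dir output directory of the run.
#' @param master_seed integer master seed; per-stage seeds are spawned
#'   from it deterministically.
#' @param ... overrides of the default fields (see the returned list).
#' @return a named list of class `run_config`.
#' @export
default_run_config <- function(out_dir = "helixtps_run", master_seed = 1L,
                               ...) {
  ref <- toy_dimer_reference()
  cfg <- list(
    out_dir = out_dir,
    master_seed = as.integer(master_seed),
    unit_system = "reduced (nm, kT, BD time)",
    # simulate: umbrella windows on D_RMS, two independent start conditions
    umbrella_centers = seq(0.05, 2.45, by = 0.15),
    umbrella_k = 100,
    umbrella_steps = 3e5,
    umbrella_thin = 20,
    dt = ref$params$dt,
    # cv / wham
    mu = ref$mu,
    mu_grid = c(0, 0.05, 0.1, 0.2, 0.4),
    bin_width = 0.02,
    wham_tol = 1e-7,
    # shooting at the inner (native-docking) barrier
    x_dagger = ref$x_dagger_2,
    basin_a = ref$basins_b2$a,
    basin_b = ref$basins_b2$b,
    select_tol = 0.02,
    n_attempts = 60,
    shoot_max_time = 40,
    shoot_thin = 10,
    # mechanism
    contact_cutoff = 0.45,
    u_cut = ref$u_cut,
    min_cond = 10,
    make_figures = FALSE)
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

#' @rdname default_run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

stage_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 7919 + stage * 104729) %%
               .Machine$integer.max)
}

pipe_log <- function(run_dir, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
  cat(line, "\n", sep = "")
  cat(line, "\n", sep = "", file = file.path(run_dir, "pipeline.log"),
      append = TRUE)
}

#' Run the synthetic-dimer TPS pipeline end to end
#'
#' Executes the stages simulate -> cv -> wham -> shoot -> rates ->
#' mechanism on the toy helix dimer, writing tab-separated tables, a JSON
#' rates report, the resolved configuration and a provenance log into
#' `config$out_dir`. Every stage caches its result (`<stage>.rds`); on
#' rerun, stages whose cache exists are skipped, so a run is resumable
#' and any stage can be redone by deleting its cache. All randomness
#' derives from `config$master_seed`, so a rerun from scratch is
#' bit-identical.
#'
#' @param config a [default_run_config()].
#' @return invisibly, a list with the per-stage results.
#' @export
run_pipeline <- function(config = default_run_config()) {
  stopifnot(inherits(config, "run_config"))
  run_dir <- config$out_dir
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  write_run_config(config, file.path(run_dir, "config.yaml"))
  pipe_log(run_dir, "pipeline start; package version ",
           as.character(utils::packageVersion("helixtps")),
           "; master seed ", config$master_seed)
  ref <- toy_dimer_reference()
  model <- ref$model

  cache <- function(stage, expr) {
    f <- file.path(run_dir, paste0(stage, ".rds"))
    if (file.exists(f)) {
      pipe_log(run_dir, "stage ", stage, ": cached, skipping")
      return(readRDS(f))
    }
    t0 <- Sys.time()
    val <- expr()
    saveRDS(val, f)
    pipe_log(run_dir, "stage ", stage, ": done in ",
             sprintf("%.1f s", as.numeric(Sys.time() - t0, units = "secs")))
    val
  }

  # --- simulate: two independent umbrella sets ("start together" = from
  # the native complex, "start separate" = from the dissociated state) ---
  sim <- cache("simulate", function() {
    lapply(c(together = 1L, separate = 2L), function(set) {
      init <- if (set == 1L) "native" else "separate"
      lapply(seq_along(config$umbrella_centers), function(i) {
        par <- langevin_params(
          dt = config$dt,
          seed = stage_seed(config$master_seed, 100L * set + i))
        simulate_toy_dimer(model, par, config$umbrella_steps,
                           initial = init, thin = config$umbrella_thin,
                           bias = list(center = config$umbrella_centers[i],
                                       k = config$umbrella_k))
      })
    })
  })

  # --- cv: hybrid coordinate per window, tab-separated tables ---
  cv <- cache("cv", function() {
    out <- lapply(names(sim), function(set) {
      lapply(seq_along(sim[[set]]), function(i) {
        tr <- sim[[set]][[i]]
        data.frame(frame = seq_along(tr$drms) - 1L,
                   time = (seq_along(tr$drms) - 1L) * tr$dt,
                   drms = tr$drms, theta = tr$theta,
                   x = hybrid_cv(tr$drms, tr$theta, config$mu))
      })
    })
    names(out) <- names(sim)
    all <- do.call(rbind, lapply(names(out), function(set)
      cbind(set = set,
            window = rep(seq_along(out[[set]]),
                         vapply(out[[set]], nrow, 1L)),
            do.call(rbind, out[[set]]))))
    write_cv_table(all, file.path(run_dir, "cv_series.tsv"))
    out
  })

  # --- wham: pooled windows, projection on X, barriers, mu scan ---
  wh <- cache("wham", function() {
    windows <- list()
    for (set in names(sim))
      for (i in seq_along(sim[[set]]))
        windows <- c(windows, list(umbrella_window(
          center = config$umbrella_centers[i], k = config$umbrella_k,
          cv = sim[[set]][[i]]$drms, id = paste0(set, "_", i))))
    # the PMF is only interpreted over the window-covered domain: frames
    # beyond the umbrella ladder carry huge, unreliable unbiasing weights
    hi <- max(config$umbrella_centers) + 0.1
    bins <- bin_spec(-config$bin_width, hi, config$bin_width)
    fit <- wham(windows, bins, tol = config$wham_tol)
    drms_all <- unlist(lapply(cv, function(set)
      lapply(set, `[[`, "drms")))
    theta_all <- unlist(lapply(cv, function(set)
      lapply(set, `[[`, "theta")))
    x_all <- drms_all + config$mu * theta_all
    xbins <- bin_spec(-0.35, hi, config$bin_width)
    pmf_x <- project_pmf(fit$weights, x_all, xbins)
    bar <- locate_barriers(pmf_x, min_n_eff = 20)
    scan <- scan_mu(fit$weights, drms_all, theta_all, config$mu_grid,
                    bin_width = config$bin_width, domain = c(-0.5, hi),
                    min_n_eff = 20)
    write_pmf(pmf_x, file.path(run_dir, "pmf_x.tsv"))
    utils::write.table(scan$table, file.path(run_dir, "mu_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (isTRUE(config$make_figures)) {
      grDevices::pdf(file.path(run_dir, "pmf_x.pdf"), width = 5, height = 4)
      plot(pmf_x, main = "F(X) from pooled umbrella windows")
      grDevices::dev.off()
    }
    list(fit = fit, pmf_x = pmf_x, barriers = bar, mu_scan = scan,
         x_all = x_all)
  })

  # --- shoot: frames near the dividing surface, conjugate pairs ---
  sh <- cache("shoot", function() {
    basins <- basin_spec(config$basin_a, config$basin_b)
    prop <- dimer_propagator(model,
                             langevin_params(dt = config$dt),
                             mu = config$mu)
    frames <- list()
    for (set in names(sim)) {
      x_set <- unlist(lapply(cv[[set]], `[[`, "x"))
      states_set <- do.call(rbind, lapply(sim[[set]], `[[`, "states"))
      idx <- select_frames(x_set, config$x_dagger, tol = config$select_tol,
                           n_frames = ceiling(config$n_attempts / 2),
                           seed = stage_seed(config$master_seed, 300L +
                                               match(set, names(sim))))
      frames <- c(frames, lapply(idx, function(j) states_set[j, ]))
    }
    ens <- shoot_ensemble(frames, prop, basins,
                          max_time = config$shoot_max_time,
                          seed = stage_seed(config$master_seed, 400L),
                          thin = config$shoot_thin,
                          surface = config$x_dagger)
    led <- attempt_ledger(ens)
    utils::write.table(led, file.path(run_dir, "attempt_ledger.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(ensemble = ens, ledger = led)
  })

  # --- rates: Eq-style reactive flux split by the PMF equilibrium constant ---
  rt <- cache("rates", function() {
    peq <- p_eq_at(wh$pmf_x, config$x_dagger)
    K <- equilibrium_constant(wh$pmf_x, config$x_dagger)
    kin <- rates_from_shooting(sh$ensemble, peq, K$K_eq)
    tf <- tp_fraction(sh$ensemble)
    tau <- tp_durations(sh$ensemble)
    rep <- list(k_b = kin$k_b, k_u = kin$k_u, se_k_b = kin$se_k_b,
                se_k_u = kin$se_k_u, flux = kin$J, K_eq = K$K_eq,
                p_eq_surface = peq, tp_fraction = tf$fraction,
                tp_fraction_of_max = tf$of_maximum,
                mean_tp_duration = tau,
                n_tp = kin$n_tp, n_classified = kin$n_classified,
                estimator = paste("2/(1/k_b+1/k_u) = p_eq(X+) *",
                                  "<theta_TP (sum 1/|v|)^-1>, band",
                                  "occupation speeds"),
                unit = config$unit_system)
    jsonlite::write_json(rep, file.path(run_dir, "rates.json"),
                         auto_unbox = TRUE, digits = NA)
    list(kinetics = kin, K = K, p_eq = peq, tp_fraction = tf, tau = tau)
  })

  # --- mechanism: p(q|TP), p(q)_nn, p(TP|q)_nn, tail curves ---
  mech <- cache("mechanism", function() {
    ens <- sh$ensemble
    cls <- vapply(ens, `[[`, character(1), "classification")
    tps <- which(cls == "TP")
    if (!length(tps)) stop("no transition paths: rerun shoot with more ",
                           "attempts (stage cache: shoot.rds)")
    par <- langevin_params(dt = config$dt)
    tp_contacts <- lapply(ens[tps], function(a) {
      st <- rbind(a$backward$states[rev(seq_len(nrow(a$backward$states))), ,
                                    drop = FALSE],
                  a$forward$states[-1, , drop = FALSE])
      dimer_contacts_cpp(dimer_cpp_par(model, par), st,
                         config$contact_cutoff)
    })
    w_tp <- path_weights(ens)[tps]
    pq_tp <- p_q_given_tp(tp_contacts, w_tp)
    # equilibrium p(q)_nn from the umbrella frames, WHAM-reweighted and
    # restricted to the non-native two-state region
    states_all <- do.call(rbind, lapply(names(sim), function(set)
      do.call(rbind, lapply(sim[[set]], `[[`, "states"))))
    nn <- nn_frames(wh$x_all, bound_interval = c(-Inf, config$basin_a[2]),
                    exclude_interval = c(config$u_cut, Inf))
    cm_nn <- dimer_contacts_cpp(dimer_cpp_par(model, par),
                                states_all[nn, , drop = FALSE],
                                config$contact_cutoff)
    pq_nn <- contact_probability(cm_nn, wh$fit$weights[nn])
    ptp_nn <- p_tp_nn(rt$tau, rt$kinetics$k_b)
    n <- model$n_beads
    pairs <- cbind(i = rep(seq_len(n), each = n),
                   j = rep(seq_len(n), times = n))
    native_mask <- paste(pairs[, 1], pairs[, 2]) %in%
      paste(model$native_pairs[, 1], model$native_pairs[, 2])
    maps <- p_tp_given_q(pq_tp, pq_nn$p, ptp_nn, native_mask,
                         n_cond = pq_nn$n_cond, min_cond = config$min_cond,
                         barrier = 2)
    tails <- tail_distribution(maps)
    write_mechanism_maps(maps, pairs, file.path(run_dir, "mechanism.tsv"))
    utils::write.table(tails, file.path(run_dir, "tails.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (isTRUE(config$make_figures)) {
      grDevices::pdf(file.path(run_dir, "mechanism.pdf"), width = 9,
                     height = 3.2)
      op <- graphics::par(mfrow = c(1, 3))
      graphics::image(seq_len(n), seq_len(n),
                      matrix(maps$p_q_tp, n, n, byrow = TRUE),
                      xlab = "residue i (chain A)",
                      ylab = "residue j (chain B)", main = "p(q|TP)")
      graphics::image(seq_len(n), seq_len(n),
                      matrix(maps$p_tp_q, n, n, byrow = TRUE),
                      xlab = "residue i (chain A)",
                      ylab = "residue j (chain B)", main = "p(TP|q)_nn")
      plot(tails$threshold, tails$n_nonnative, type = "s", col = 2,
           xlab = "threshold", ylab = "contacts above", main = "tails")
      graphics::lines(tails$threshold, tails$n_native, type = "s")
      graphics::par(op)
      grDevices::dev.off()
    }
    list(maps = maps, tails = tails, pairs = pairs)
  })

  pipe_log(run_dir, "pipeline complete")
  invisible(list(simulate = sim, cv = cv, wham = wh, shoot = sh,
                 rates = rt, mechanism = mech, run_dir = run_dir))
}
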