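# ---------------------------------------------------------------------------
# Experiment configuration, validation and the run driver: YAML configs
# with schema checking, per-seed CSV records and JSON run metadata.
# ---------------------------------------------------------------------------

.config_schema <- list(
  task = c("cartpole", "dms", "yinyang", "teacher_student",
           "generative_images", "phi_prime_demo"),
  top_keys = c("task", "scale", "seeds", "epochs", "network", "task_params",
               "output"),
  network_keys = c("g_l", "g_rep", "g_err", "g_den", "g_nudge", "C_m", "dt",
                   "T_pres", "taur_r", "sigma_L", "b_noise", "eta",
                   "settle_steps", "activation", "hierarchy", "n_R", "n_E"),
  task_param_keys = c("complexity", "n_train", "n_val", "n_test", "side",
                      "hidden", "variant", "n_episodes", "sigma_act",
                      "apply_to", "sigma_xi", "tau_xi", "T_pres_ticks",
                      "n_pres", "eval_every")
)

#' Validate and normalise an experiment configuration
#'
#' Reads a YAML file (or takes a list), rejects unknown keys, checks
#' value ranges (conductances >= 0, `dt > 0`, positive epochs and seeds),
#' fills defaults, and computes the derived quantities `g_tot` and the
#' membrane time constants, which are echoed in the result. A missing
#' `taur_r` defaults to `tau_m` (the quasi-instantaneous preset).
#'
#' @param config Path to a YAML file or a configuration list.
#' @return The normalised configuration (class `"mc_config"`), with the
#'   derived values under `$derived`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .config_schema$top_keys)
  if (length(unknown) > 0L)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$task) || !config$task %in% .config_schema$task)
    stop("config must name a task out of: ",
         paste(.config_schema$task, collapse = ", "))
  config$scale <- if (is.null(config$scale)) "paper" else
    match.arg(config$scale, c("paper", "smoke"))
  config$seeds <- if (is.null(config$seeds)) 1L else as.integer(config$seeds)
  if (any(config$seeds < 0)) stop("seeds must be nonnegative integers")
  config$epochs <- if (is.null(config$epochs)) 1L else as.integer(config$epochs)
  if (config$epochs < 1L) stop("epochs must be >= 1")

  nw <- if (is.null(config$network)) list() else config$network
  unknown <- setdiff(names(nw), .config_schema$network_keys)
  if (length(unknown) > 0L)
    stop("unknown network key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(g_l = 0.03, g_rep = 0.1, g_err = 0.06, g_den = 0.1,
                   g_nudge = 0.06, C_m = 1, dt = 0.01, T_pres = 0.2,
                   taur_r = "tau_m", sigma_L = 0.3, b_noise = 0.5,
                   eta = 1, settle_steps = 10L, activation = "tanh",
                   hierarchy = "strict")
  for (k in names(defaults)) if (is.null(nw[[k]])) nw[[k]] <- defaults[[k]]
  if (nw$dt <= 0) stop("validation error: dt must be > 0")
  if (nw$T_pres < nw$dt) stop("validation error: T_pres must be >= dt")
  for (k in c("g_l", "g_rep", "g_err", "g_den", "g_nudge"))
    if (nw[[k]] < 0) stop("validation error: negative conductance ", k)
  if (!is.null(nw$n_R) && !is.null(nw$n_E) && length(nw$n_R) != length(nw$n_E))
    stop("validation error: n_R and n_E must have equal length")
  cond <- conductances(nw$g_l, nw$g_rep, nw$g_err, nw$g_den, nw$g_nudge, nw$C_m)
  config$network <- nw

  tp <- if (is.null(config$task_params)) list() else config$task_params
  unknown <- setdiff(names(tp), .config_schema$task_param_keys)
  if (length(unknown) > 0L)
    stop("unknown task_params key(s): ", paste(unknown, collapse = ", "))
  config$task_params <- tp

  config$derived <- list(g_tot = cond$g_tot, tau_m_r = cond$tau_m_r,
                         tau_m_E_hidden = cond$tau_m_E_hidden,
                         tau_m_E_output = cond$tau_m_E_output,
                         taur_r = if (identical(nw$taur_r, "tau_m"))
                           cond$tau_m_r else as.numeric(nw$taur_r))
  class(config) <- "mc_config"
  config
}

#' @export
print.mc_config <- function(x, ...) {
  cat(sprintf("<mc_config: %s (%s scale), %d seed(s), %d epoch(s)>\n",
              x$task, x$scale, length(x$seeds), x$epochs))
  cat(sprintf("  tau_m^r = %.4g, tau_r^r = %.4g, g_tot = %g\n",
              x$derived$tau_m_r, x$derived$taur_r, x$derived$g_tot))
  invisible(x)
}

#' Serialise a configuration to YAML
#' @param config A validated configuration.
#' @param path Output file.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$derived <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

.config_hash <- function(config) {
  x <- unclass(config); x$derived <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

# build the network and data for one seed of a configured task
.task_setup <- function(config, seed) {
  nw <- config$network; tp <- config$task_params
  smoke <- config$scale == "smoke"
  set.seed(seed)
  switch(config$task,
    teacher_student = {
      cx <- if (is.null(tp$complexity)) 1L else as.integer(tp$complexity)
      n <- if (smoke) 50L else 100L
      task <- generate_teacher_student(cx, sizes = rep(n, 3))
      net <- ts_network(2^(cx:0), eta = nw$eta, sigma_L = nw$sigma_L,
                        b_noise = nw$b_noise)
      list(net = net, train = task$train, eval = task$test,
           metrics = "mse_loss")
    },
    dms = {
      n <- if (smoke) 20L else 50L
      net <- dms_network(eta = nw$eta, sigma_L = nw$sigma_L)
      list(net = net, train = generate_dms(n),
           eval = generate_dms(n, split = "test"),
           metrics = c("mse_loss", "accuracy"))
    },
    yinyang = {
      n <- if (smoke) 100L else 1000L
      net <- yinyang_network(eta = nw$eta)
      list(net = net, train = generate_yinyang(n),
           eval = generate_yinyang(if (smoke) 100L else 1000L, split = "test"),
           metrics = c("mse_loss", "accuracy"))
    },
    cartpole = {
      variant <- if (is.null(tp$variant)) "realistic" else tp$variant
      ctrl <- lqr_gain()
      f_scale <- 1.5 * sum(abs(ctrl$K)) # keeps scaled targets inside (-1, 1)
      ds <- lqr_teacher_dataset(ctrl, n = if (smoke) 100L else 500L)
      ds$targets <- ds$targets / f_scale
      net <- cartpole_network(variant, eta = nw$eta)
      list(net = net, train = ds, eval = NULL, metrics = "mse_loss",
           ctrl = ctrl, force_scale = f_scale)
    },
    generative_images = {
      side <- if (is.null(tp$side)) (if (smoke) 8L else 28L) else as.integer(tp$side)
      hidden <- if (is.null(tp$hidden)) side^2 else unlist(tp$hidden)
      task <- generate_image_task("synthetic", side = side)
      net <- generative_network(side, hidden, hierarchy = nw$hierarchy,
                                eta = nw$eta, sigma_L = nw$sigma_L)
      list(net = net, train = task$data, eval = task$data,
           metrics = "mse_loss")
    },
    stop("task has no network setup: ", config$task))
}

#' Run a configured experiment
#'
#' Executes the task protocol over all seeds and writes, into the output
#' directory, a long-format CSV of per-epoch metrics (`seed, epoch,
#' split, metric, value`) and a JSON metadata file carrying the seed
#' list, a configuration hash and the package version. Refuses to run
#' into an existing output directory unless `overwrite = TRUE`.
#'
#' @param config A YAML path or configuration list (validated first).
#' @param overwrite Allow writing into an existing output directory.
#' @return Invisibly, the list of per-seed results.
#' @export
run_experiment <- function(config, overwrite = FALSE) {
  config <- validate_config(config)
  out <- if (is.null(config$output)) file.path("results", config$task) else config$output
  if (dir.exists(out) && !overwrite)
    stop("output directory exists: ", out, " (use overwrite = TRUE)")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  if (config$task == "phi_prime_demo") {
    tp <- config$task_params
    prof <- phi_prime_profile(
      sigma_xi = if (is.null(tp$sigma_xi)) 0.05 else tp$sigma_xi,
      tau_xi = if (is.null(tp$tau_xi)) 10 else tp$tau_xi,
      T_pres = if (is.null(tp$T_pres_ticks)) 100 else tp$T_pres_ticks,
      n_pres = if (is.null(tp$n_pres)) 20 else tp$n_pres)
    utils::write.csv(prof, file.path(out, "phi_prime.csv"), row.names = FALSE)
    results <- list(profile = prof)
  } else {
    results <- lapply(config$seeds, function(seed) {
      setup <- .task_setup(config, seed)
      ev <- config$task_params$eval_every
      fit <- mc_fit(setup$net, setup$train, epochs = config$epochs,
                    eval_data = setup$eval,
                    eval_every = if (is.null(ev)) max(1L, config$epochs %/% 20L)
                                 else as.integer(ev),
                    metrics = setup$metrics)
      rec <- cbind(seed = seed, fit$record)
      if (config$task == "cartpole") {
        ctl0 <- mc_controller(fit$net)
        ctl <- function(s) setup$force_scale * ctl0(s)
        roll <- cartpole_rollout(ctl, n_episodes = 5,
                                 params = cartpole_params())
        rec <- rbind(rec, data.frame(seed = seed, epoch = config$epochs,
                                     split = "test", metric = "penalty_log",
                                     value = roll$penalty))
      }
      list(fit = fit, record = rec)
    })
    rec <- do.call(rbind, lapply(results, `[[`, "record"))
    utils::write.csv(rec, file.path(out, "record.csv"), row.names = FALSE)
  }

  meta <- list(task = config$task, scale = config$scale,
               seeds = config$seeds, epochs = config$epochs,
               config_hash = .config_hash(config),
               package_version = as.character(utils::packageVersion("errnet")),
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(meta, file.path(out, "meta.json"), auto_unbox = TRUE)
  invisible(results)
}

#' Closed-loop controller callback from a trained network
#'
#' Wraps a microcircuit as a `state -> scalar output` function for the
#' cart-pole loop: each call clamps the state vector as input, advances
#' the network by one tick (reference dynamics, no target, plasticity
#' off) and returns the output rate. The network's internal state
#' persists between calls, matching one controller tick per plant step.
#'
#' @param net An [mc_network()] (typically from a fitted model).
#' @return A closure `function(state) -> force` (unscaled).
#' @export
mc_controller <- function(net) {
  st <- mc_state(net)
  function(state) {
    st <<- mc_tick(net, st, as.numeric(state))$state
    st$r_r[[net$target_area]][1]
  }
}

#' Aggregate experiment records into a summary table
#'
#' @param paths Record CSV files (as written by [run_experiment()]).
#' @return Data frame with the final-epoch value of every metric,
#'   summarised over seeds (median, mean, sd).
#' @export
report_records <- function(paths) {
  rec <- do.call(rbind, lapply(paths, utils::read.csv))
  fin <- rec[rec$epoch == ave(rec$epoch, rec$seed, rec$split, rec$metric,
                              FUN = max), ]
  agg <- aggregate(value ~ split + metric, fin,
                   function(v) c(median = stats::median(v), mean = mean(v),
                                 sd = stats::sd(v)))
  do.call(data.frame, agg)
}
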