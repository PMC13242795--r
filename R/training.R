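# Training: geometry-enhanced masking, the Adam-updated training step on
# batched disjoint point clouds, and the user-facing fitting function
# pif() returning a classed model object.

#' Geometry-enhanced masking configuration
#'
#' With probability `p_activate` the masking mechanism fires for a
#' training instance; given activation, each ligand atom independently
#' becomes a reconstruction target with probability `p_atom`, and the
#' remaining atoms enter the model as fixed conditioning context. Without
#' activation the instance trains de novo (all atoms targets).
#'
#' @param p_activate activation probability, default 0.3.
#' @param p_atom per-atom masking probability given activation, default 0.3.
#' @return an object of class `"mask_config"`.
#' @export
mask_config <- function(p_activate = 0.3, p_atom = 0.3) {
  if (p_activate < 0 || p_activate > 1 || p_atom < 0 || p_atom > 1)
    stop_pif("mask probabilities must lie in [0, 1]")
  structure(list(p_activate = p_activate, p_atom = p_atom),
            class = "mask_config")
}

#' Draw a geometry mask for one molecule
#'
#' @param molecule a [pif_molecule()].
#' @param cfg a [mask_config()].
#' @return list with `target` (indices to reconstruct), `context`
#'   (fixed-atom indices) and `active` (whether masking fired). A draw
#'   that selects zero targets is redrawn once, then falls back to de novo
#'   (all atoms targets, empty context).
#' @export
apply_geometry_mask <- function(molecule, cfg = mask_config()) {
  n <- nrow(molecule$coords)
  if (n < 1L) stop_pif("molecule must have at least one atom")
  denovo <- list(target = seq_len(n), context = integer(0), active = FALSE)
  if (stats::runif(1) >= cfg$p_activate) return(denovo)
  for (attempt in 1:2) {
    tgt <- which(stats::runif(n) < cfg$p_atom)
    if (length(tgt) && length(tgt) < n)
      return(list(target = tgt, context = setdiff(seq_len(n), tgt),
                  active = TRUE))
    if (length(tgt) == n)   # degenerate full mask: treat as de novo
      return(list(target = seq_len(n), context = integer(0), active = TRUE))
  }
  list(target = seq_len(n), context = integer(0), active = TRUE)
}

# assemble one training instance: draw t, mask, interpolate, sample.
# Returns per-atom arrays for the batched predictor input plus the truth
# needed by the loss. Coordinates are centered on the conditioning frame
# (pocket centroid when present, else ligand centroid).
build_training_instance <- function(mol, pocket, cfg) {
  n <- nrow(mol$coords)
  t_i <- stats::runif(1, 0, cfg$t_max)
  msk <- apply_geometry_mask(mol, cfg$mask)
  center <- if (!is.null(pocket)) colMeans(pocket$coords) else colMeans(mol$coords)
  xd <- sweep(mol$coords, 2L, center)
  cp <- interpolate_continuous(xd[msk$target, , drop = FALSE], cfg$prior,
                               t_i, cfg$schedule)
  tp <- interpolate_discrete(mol$types[msk$target], cfg$prior$K, t_i, cfg$schedule)
  x_s <- if (cfg$prior$family == "gaussian") sample_gaussian(cp) else sample_laplace(cp)
  v_s <- sample_dirichlet(tp)$p
  # fixed context: masked-out ligand atoms, then pocket atoms
  ctx_x <- xd[msk$context, , drop = FALSE]
  ctx_v <- mol$types[msk$context]
  if (!is.null(pocket)) {
    ctx_x <- rbind(ctx_x, sweep(pocket$coords, 2L, center))
    ctx_v <- c(ctx_v, pocket$types)
  }
  m <- nrow(ctx_x)
  list(coords = rbind(x_s, ctx_x),
       type_probs = rbind(v_s, make_dirac_discrete(ctx_v, cfg$prior$K)$alpha),
       fixed = c(rep(FALSE, length(msk$target)), rep(TRUE, m)),
       t = t_i,
       mu_true = xd[msk$target, , drop = FALSE],
       types_true = mol$types[msk$target],
       n_target = length(msk$target),
       target_ids = msk$target,
       mask_active = msk$active)
}

# analytic gradient of the batch loss wrt (mu_hat, alpha_hat); also the
# loss value. Rows for fixed atoms stay zero.
batch_loss_grads <- function(pred, inst_list, atom_offsets, cfg) {
  B <- length(inst_list)
  n_all <- nrow(pred$mu_hat)
  K <- cfg$prior$K
  grad_mu <- matrix(0, n_all, 3)
  grad_alpha <- matrix(0, n_all, K)
  lx_tot <- lv_tot <- 0
  for (bi in seq_len(B)) {
    inst <- inst_list[[bi]]
    rows <- atom_offsets[bi] + seq_len(inst$n_target)   # generated atoms first
    mu_hat <- pred$mu_hat[rows, , drop = FALSE]
    a_hat_sx <- pred$alpha_hat[rows, , drop = FALSE]
    nt <- inst$n_target
    f <- schedule_value(inst$t, cfg$schedule)
    dmu <- mu_hat - inst$mu_true
    if (cfg$prior$family == "gaussian") {
      w <- if (cfg$schedule$kind == "exponential")
        continuous_time_weight(inst$t, cfg$schedule$gamma, cfg$prior$eps0)
      else f^2 / (2 * max((1 - f)^2, 1e-12) * cfg$prior$eps0^2)
      lx <- w * mean(rowSums(dmu^2))
      gmu <- (2 * w / nt) * dmu
    } else {
      b_t <- (1 - f) * cfg$prior$beta0
      z <- abs(dmu) / b_t
      lx <- mean(rowSums(z + exp(-z) - 1))
      gmu <- sign(dmu) * (1 - exp(-z)) / (b_t * nt)
    }
    a_true <- f * make_dirac_discrete(inst$types_true, K)$alpha + (1 - f) / K
    a_hat <- f * a_hat_sx + (1 - f) / K
    if (cfg$dirichlet_form == "printed") {
      per <- rowSums(lgamma(a_true) - lgamma(a_hat) +
                       (a_hat - a_true) * (digamma(a_hat) - digamma(1)))
      lv <- mean(per)
      dl_da <- -digamma(1) + (a_hat - a_true) * trigamma(a_hat)
    } else {
      lv <- mean(kl_dirichlet_exact(dirichlet_params(a_hat),
                                    dirichlet_params(a_true)))
      a0 <- rowSums(a_hat)
      dl_da <- (a_hat - a_true) * trigamma(a_hat) -
        trigamma(a0) * rowSums(a_hat - a_true)
    }
    galpha <- (f / nt) * dl_da
    grad_mu[rows, ] <- (cfg$weights$lambda_x / B) * gmu
    grad_alpha[rows, ] <- (cfg$weights$lambda_v / B) * galpha
    lx_tot <- lx_tot + lx
    lv_tot <- lv_tot + lv
  }
  list(grad_mu = grad_mu, grad_alpha = grad_alpha,
       loss = (cfg$weights$lambda_x * lx_tot + cfg$weights$lambda_v * lv_tot) / B,
       loss_x = lx_tot / B, loss_v = lv_tot / B)
}

adam_init <- function(par) list(m = lapply(par, function(p) p * 0),
                                v = lapply(par, function(p) p * 0), step = 0L)

adam_update <- function(par, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  opt$step <- opt$step + 1L
  c1 <- 1 - beta1^opt$step
  c2 <- 1 - beta2^opt$step
  for (nm in names(par)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    par[[nm]] <- par[[nm]] -
      lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
  }
  list(par = par, opt = opt)
}

#' One training step on a batch of molecules
#'
#' Draws a time per instance, applies the geometry mask, interpolates the
#' target parameters, samples coordinates/types at time t, runs the
#' predictor on the batched disjoint cloud, and (for a trainable network)
#' applies one Adam update from the exact analytic gradients. Uses the
#' current RNG stream. Aborts with diagnostics on a non-finite loss.
#'
#' @param model a `"pif_net"` or `"pif_oracle"` (the oracle computes the
#'   loss only; no update).
#' @param batch named list of [pif_molecule()].
#' @param cfg list of training configuration: `schedule`, `prior`,
#'   `weights`, `mask`, `t_max`, `dirichlet_form`, `lr`.
#' @param opt Adam optimizer state (from a previous step), or `NULL`.
#' @param pockets optional list of pocket molecules parallel to `batch`.
#' @return list with the updated `model` and `opt`, pre-update `loss`,
#'   components `loss_x`/`loss_v`, and `mask_active` fraction.
#' @export
training_step <- function(model, batch, cfg, opt = NULL, pockets = NULL) {
  insts <- lapply(seq_along(batch), function(i)
    build_training_instance(batch[[i]],
                            if (is.null(pockets)) NULL else pockets[[i]], cfg))
  n_atoms <- vapply(insts, function(z) nrow(z$coords), integer(1))
  offsets <- cumsum(c(0L, n_atoms[-length(n_atoms)]))
  input <- predictor_input(
    coords = do.call(rbind, lapply(insts, `[[`, "coords")),
    type_probs = do.call(rbind, lapply(insts, `[[`, "type_probs")),
    t = rep(vapply(insts, `[[`, numeric(1), "t"), n_atoms),
    fixed = unlist(lapply(insts, `[[`, "fixed")),
    block = rep(seq_along(insts), n_atoms))
  if (inherits(model, "pif_oracle")) {
    # evaluate only, instance by instance
    loss <- 0; lx <- 0; lv <- 0
    for (bi in seq_along(insts)) {
      inst <- insts[[bi]]
      rows <- offsets[bi] + seq_len(n_atoms[bi])
      sub <- predictor_input(input$coords[rows, , drop = FALSE],
                             input$type_probs[rows, , drop = FALSE],
                             inst$t, input$fixed[rows],
                             instance = names(batch)[bi],
                             atom_ids = apply_ids_for(inst))
      pr <- pif_predict(model, sub)
      bl <- batch_loss_grads(pr, list(inst), 0L, cfg)
      loss <- loss + bl$loss; lx <- lx + bl$loss_x; lv <- lv + bl$loss_v
    }
    B <- length(insts)
    return(list(model = model, opt = opt, loss = loss / B,
                loss_x = lx / B, loss_v = lv / B,
                mask_active = mean(vapply(insts, `[[`, logical(1), "mask_active"))))
  }
  fw <- net_forward(model, input, keep_cache = TRUE)
  bl <- batch_loss_grads(fw, insts, offsets, cfg)
  if (!is.finite(bl$loss)) {
    stop_pif("non-finite loss at t = ",
             paste(signif(vapply(insts, `[[`, numeric(1), "t"), 3), collapse = ", "),
             "; |par| = ", signif(sqrt(sum(unlist(model$par)^2)), 4))
  }
  grads <- net_backward(model, fw$cache, bl$grad_mu, bl$grad_alpha)
  # global-norm gradient clipping: the time weight grows like 1/gamma^t,
  # so raw gradients are heavy-tailed across t draws; clipping keeps the
  # occasional near-endpoint draw from destabilizing the run
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(gnorm) && gnorm > 10)
    grads <- lapply(grads, function(g) g * (10 / gnorm))
  upd <- adam_update(model$par, grads, opt %||% adam_init(model$par), cfg$lr)
  model$par <- upd$par
  list(model = model, opt = upd$opt, loss = bl$loss,
       loss_x = bl$loss_x, loss_v = bl$loss_v,
       mask_active = mean(vapply(insts, `[[`, logical(1), "mask_active")))
}

# oracle bookkeeping: which reference-molecule atoms the generated rows map to
apply_ids_for <- function(inst) {
  # generated rows are the target atoms in order
  inst$target_ids %||% seq_len(inst$n_target)
}

#' Fit a parameter interpolation flow model
#'
#' Trains the reference point-cloud network to predict data-endpoint
#' parameters (exact coordinates, one-hot types) from samples drawn along
#' the interpolation path, with geometry-enhanced masking. Fully
#' deterministic given `(seed, config, data)`.
#'
#' @param data list of [pif_molecule()] training ligands (each centered
#'   internally on its conditioning frame).
#' @param K number of atom-type classes; defaults to the data's.
#' @param schedule a [pif_schedule()].
#' @param prior a [pif_prior()].
#' @param weights a [pif_loss_weights()].
#' @param mask a [mask_config()].
#' @param steps total optimizer steps (>= 1), default 2000.
#' @param batch_size molecules per step, default 8.
#' @param lr Adam learning rate, default 1e-3.
#' @param hidden,layers,knn_k network size (see [pif_network()]).
#' @param dirichlet_form `"printed"` or `"exact_kl"` (see [loss_discrete()]).
#' @param t_max training times are drawn uniformly on `[0, t_max]`,
#'   default 0.99, keeping the degenerate data endpoint out of the loss.
#' @param log_every record a log row every this many steps.
#' @param lr_horizon cosine-decay horizon in steps; defaults to `steps`.
#'   A run meant to be interrupted and resumed should fix the horizon at
#'   the planned total so the decay profile is unchanged across resumes.
#' @param seed master seed; network init and the training stream derive
#'   from it.
#' @param pockets optional list of pocket context molecules parallel to
#'   `data`.
#' @param resume a previous `"pif"` fit to continue (training proceeds to
#'   `steps` total steps with the saved optimizer and RNG state).
#' @return an object of class `"pif"`: the trained network (`$net`), the
#'   resolved config (`$config`, with hash), a training log data frame
#'   (`$log`), data statistics (`$data_stats`) and the seed.
#' @export
pif <- function(data, K = NULL,
                schedule = pif_schedule(), prior = NULL,
                weights = pif_loss_weights(), mask = mask_config(),
                steps = 2000, batch_size = 8, lr = 1e-3,
                hidden = 32, layers = 2, knn_k = 16,
                dirichlet_form = c("printed", "exact_kl"),
                t_max = 0.99, log_every = 50, seed = 1,
                lr_horizon = NULL, pockets = NULL, resume = NULL) {
  dirichlet_form <- match.arg(dirichlet_form)
  if (inherits(data, "pif_molecule")) data <- list(mol_1 = data)
  if (is.null(names(data))) names(data) <- paste0("mol_", seq_along(data))
  K <- as.integer(K %||% data[[1]]$K)
  prior <- prior %||% pif_prior(K = K)
  if (prior$K != K) stop_pif("prior K does not match data K")
  steps <- as.integer(steps)
  if (steps < 1L) stop_pif("steps must be >= 1")
  lr_horizon <- as.integer(lr_horizon %||%
                             (if (is.null(resume)) steps
                              else resume$config$lr_horizon))
  cfg <- list(schedule = schedule, prior = prior, weights = weights,
              mask = mask, t_max = t_max, dirichlet_form = dirichlet_form,
              lr = lr, lr_horizon = lr_horizon, steps = steps,
              batch_size = as.integer(batch_size),
              hidden = hidden, layers = layers, knn_k = knn_k, seed = seed)
  cfg$hash <- config_hash(cfg[setdiff(names(cfg), "hash")])
  if (is.null(resume)) {
    net <- pif_network(K, hidden = hidden, layers = layers, knn_k = knn_k,
                       seed = derive_seed(seed, 0L))
    opt <- adam_init(net$par)
    ema <- net$par
    start_step <- 0L
    log_rows <- list()
    rng <- NULL
  } else {
    stopifnot(inherits(resume, "pif"))
    net <- resume$net
    net$par <- resume$par_raw %||% resume$net$par
    ema <- resume$ema %||% net$par
    opt <- resume$opt
    start_step <- resume$steps_done
    log_rows <- resume$log_rows
    rng <- resume$rng_state
  }
  if (start_step >= steps)
    stop_pif("resume: fit already has ", start_step, " steps")
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  if (is.null(rng)) set.seed(derive_seed(seed, 1L))
  else assign(".Random.seed", rng, globalenv())
  for (s in (start_step + 1L):steps) {
    idx <- sample.int(length(data), min(cfg$batch_size, length(data)),
                      replace = length(data) < cfg$batch_size)
    # cosine decay to lr/20 over the run: late training runs at a small
    # step size so the final weights sit at a sharp optimum rather than
    # oscillating around it
    frac <- min(s, lr_horizon) / lr_horizon
    cfg$lr <- lr / 20 + 0.5 * (lr - lr / 20) * (1 + cos(pi * frac))
    res <- training_step(net, data[idx], cfg, opt,
                         pockets = if (is.null(pockets)) NULL else pockets[idx])
    net <- res$model; opt <- res$opt
    # Polyak averaging: the exported weights are an exponential moving
    # average of the iterates, which damps the small-batch optimization
    # noise that otherwise leaves run-to-run quality scatter
    for (nm in names(ema))
      ema[[nm]] <- 0.998 * ema[[nm]] + 0.002 * net$par[[nm]]
    if (s %% log_every == 0L || s == 1L || s == steps)
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(step = s, loss = res$loss, loss_x = res$loss_x,
                   loss_v = res$loss_v, mask_active = res$mask_active)
  }
  rng_state <- get(".Random.seed", globalenv())
  if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old_seed, globalenv())
  sizes <- vapply(data, function(m) nrow(m$coords), integer(1))
  type_marginal <- tabulate(unlist(lapply(data, `[[`, "types")), nbins = K)
  par_raw <- net$par
  net$par <- ema
  structure(list(net = net, par_raw = par_raw, ema = ema, opt = opt,
                 config = cfg,
                 log = do.call(rbind, log_rows), log_rows = log_rows,
                 steps_done = steps, rng_state = rng_state,
                 data_stats = list(
                   n_molecules = length(data),
                   size_table = table(sizes),
                   type_marginal = type_marginal / sum(type_marginal)),
                 seed = seed, call = match.call()),
            class = "pif")
}

#' @export
print.pif <- function(x, ...) {
  cat("Parameter interpolation flow model\n")
  cat("  prior: ", x$config$prior$family,
      " (eps0 = ", x$config$prior$eps0, ", beta0 = ", x$config$prior$beta0,
      ", K = ", x$config$prior$K, ")\n", sep = "")
  cat("  schedule: ", x$config$schedule$kind,
      if (x$config$schedule$kind == "exponential")
        paste0(" (gamma = ", x$config$schedule$gamma, ")") else "", "\n", sep = "")
  cat("  trained ", x$steps_done, " steps on ", x$data_stats$n_molecules,
      " molecules; final loss ", signif(utils::tail(x$log$loss, 1), 4),
      "\n", sep = "")
  cat("  config hash ", x$config$hash, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @export
summary.pif <- function(object, ...) {
  lg <- object$log
  out <- list(config = object$config, data_stats = object$data_stats,
              initial_loss = lg$loss[1], final_loss = utils::tail(lg$loss, 1),
              mask_active_rate = mean(lg$mask_active),
              n_parameters = sum(lengths(object$net$par)))
  class(out) <- "summary.pif"
  out
}

#' @export
print.summary.pif <- function(x, ...) {
  cat("pif model summary\n")
  cat("  parameters:        ", x$n_parameters, "\n")
  cat("  initial loss:      ", signif(x$initial_loss, 5), "\n")
  cat("  final loss:        ", signif(x$final_loss, 5), "\n")
  cat("  mask active rate:  ", signif(x$mask_active_rate, 3), "\n")
  cat("  molecules:         ", x$data_stats$n_molecules, "\n")
  invisible(x)
}

#' @export
coef.pif <- function(object, ...) {
  unlist(object$net$par)
}

#' @export
plot.pif <- function(x, ...) {
  graphics::plot(x$log$step, x$log$loss, type = "l", xlab = "step",
                 ylab = "training loss", main = "pif training trajectory", ...)
  invisible(x)
}

#' Predict data-endpoint parameters with a fitted model
#'
#' Runs the trained predictor on a [predictor_input()], or on a molecule
#' perturbed to time `t` along the interpolation path.
#'
#' @param object a fitted `"pif"`.
#' @param input a [predictor_input()], or a [pif_molecule()].
#' @param t time used when `input` is a molecule (default 0.9).
#' @param ... unused.
#' @return list with `mu_hat` and `alpha_hat`.
#' @export
predict.pif <- function(object, input, t = 0.9, ...) {
  if (inherits(input, "pif_molecule")) {
    cfg <- object$config
    xd <- sweep(input$coords, 2L, colMeans(input$coords))
    cp <- interpolate_continuous(xd, cfg$prior, t, cfg$schedule)
    tp <- interpolate_discrete(input$types, cfg$prior$K, t, cfg$schedule)
    input <- predictor_input(
      coords = if (cfg$prior$family == "gaussian") sample_gaussian(cp)
               else sample_laplace(cp),
      type_probs = sample_dirichlet(tp)$p, t = t)
  }
  pif_predict(object$net, input)
}

#' Denoising residuals of a fitted model
#'
#' For each training-style molecule, perturbs it to time `t`, predicts the
#' data endpoint, and returns per-atom coordinate errors.
#'
#' @param object a fitted `"pif"`.
#' @param data list of [pif_molecule()] to evaluate on.
#' @param t evaluation time (default 0.9; late times probe fine structure).
#' @param seed RNG seed for the perturbation draws.
#' @param ... unused.
#' @return numeric vector of per-atom Euclidean errors (Angstrom).
#' @export
residuals.pif <- function(object, data, t = 0.9, seed = 1, ...) {
  if (inherits(data, "pif_molecule")) data <- list(data)
  with_seed(seed, {
    unlist(lapply(data, function(mol) {
      xd <- sweep(mol$coords, 2L, colMeans(mol$coords))
      pr <- predict.pif(object, mol, t = t)
      sqrt(rowSums((pr$mu_hat - xd)^2))
    }))
  })
}
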