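# Training losses: frame-aligned point error (FAPE) reformulated for rigid
# docking, intermediate per-block FAPE, and a Kabsch RMSD term.
#
# For docking, FAPE splits into two components evaluated on the ligand
# atoms: alignment on the ligand atom frames measures internal ligand
# geometry, alignment on the (fixed, given) residue frames measures
# placement in the pocket. The protein contributes no points because it is
# rigid and known.

# Kabsch optimal proper-rotation superposition. Returns rotation R mapping
# centered pred onto centered target, centered point sets and the RMSD.
.kabsch_core <- function(pred, target) {
  pred <- matrix(as.numeric(pred), ncol = 3)
  target <- matrix(as.numeric(target), ncol = 3)
  cp <- colMeans(pred); cq <- colMeans(target)
  P <- sweep(pred, 2, cp); Q <- sweep(target, 2, cq)
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  U <- P %*% t(R) - Q
  list(R = R, pc = P, qc = Q, rmsd = sqrt(mean(rowSums(U * U))))
}

#' Kabsch RMSD
#'
#' Ligand RMSD after optimal proper-rotation superposition of predicted
#' onto target coordinates (reflections excluded, so chirality is
#' preserved). Always at most the naive RMSD. Degenerate point sets (fewer
#' than 3 points, or collinear) have no unique rotation; the naive RMSD is
#' returned with a warning.
#'
#' @param pred,target n x 3 coordinate matrices.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(pred, target) {
  pred <- matrix(as.numeric(pred), ncol = 3)
  target <- matrix(as.numeric(target), ncol = 3)
  stopifnot(nrow(pred) == nrow(target))
  degenerate <- nrow(pred) < 3L
  if (!degenerate) {
    P <- sweep(pred, 2, colMeans(pred))
    degenerate <- qr(P)$rank < 2L
  }
  if (degenerate) {
    warning("degenerate point set: falling back to naive RMSD", call. = FALSE)
    return(naive_rmsd(pred, target))
  }
  .kabsch_core(pred, target)$rmsd
}

#' Naive (in-place) RMSD
#' @param pred,target n x 3 coordinate matrices.
#' @return RMSD in Angstrom without superposition.
#' @export
naive_rmsd <- function(pred, target) {
  D <- matrix(as.numeric(pred), ncol = 3) - matrix(as.numeric(target), ncol = 3)
  sqrt(mean(rowSums(D * D)))
}

# Express points in each target frame: Nf x n_pts x 3 array.
.local_coords <- function(coords, frames) {
  fa <- if (is.list(frames) && !is.null(frames$R)) frames else frames_to_arrays(frames)
  nf <- dim(fa$R)[3]
  out <- array(0, c(nf, nrow(coords), 3))
  for (f in seq_len(nf)) {
    out[f, , ] <- sweep(coords, 2, fa$t[f, ]) %*% fa$R[, , f]
  }
  out
}

#' Frame-aligned point error
#'
#' For each frame, predicted points are expressed in the predicted frame
#' and target points in the corresponding target frame; the pointwise
#' distances are clamped at `clamp`, averaged over points and frames, and
#' divided by `scale`.
#'
#' @param pred_coords,target_coords n x 3 coordinate matrices.
#' @param frames_pred,frames_target lists of [rigid_transform()] (same
#'   length).
#' @param clamp clamp distance in Angstrom (default 10).
#' @param scale normalization in Angstrom (default 10).
#' @return The FAPE value (Angstrom / scale).
#' @export
fape <- function(pred_coords, target_coords, frames_pred, frames_target,
                 clamp = 10, scale = 10) {
  pred_coords <- matrix(as.numeric(pred_coords), ncol = 3)
  target_coords <- matrix(as.numeric(target_coords), ncol = 3)
  if (length(frames_pred) == 0L || nrow(pred_coords) == 0L) {
    rlang::abort("FAPE needs at least one frame and one point",
                 class = "fd_empty_error")
  }
  stopifnot(length(frames_pred) == length(frames_target),
            nrow(pred_coords) == nrow(target_coords))
  fp <- frames_to_arrays(frames_pred)
  tl <- .local_coords(target_coords, frames_target)
  ad_fape(pred_coords, fp$R, tl, clamp, scale, origin_const = fp$t)
}

#' Docking FAPE decomposition
#'
#' Evaluates FAPE on the ligand atoms twice: aligned on the ligand atom
#' frames (internal-geometry component) and aligned on the residue frames
#' (pocket-placement component). Since the protein is held fixed, the
#' predicted and target residue frames coincide.
#'
#' @param pred_coords,target_coords ligand coordinates (n_atoms x 3).
#' @param ligand A [ligand_graph()] (frames built per atom).
#' @param residue_frames list of residue [rigid_transform()].
#' @param clamp,scale FAPE clamp and scale (Angstrom).
#' @return `list(ligand_frames = <value>, residue_frames = <value>)`.
#' @export
docking_fape <- function(pred_coords, target_coords, ligand, residue_frames,
                         clamp = 10, scale = 10) {
  fp <- build_ligand_frames(ligand, coords = pred_coords)$frames
  ft <- build_ligand_frames(ligand, coords = target_coords)$frames
  list(
    ligand_frames = fape(pred_coords, target_coords, fp, ft, clamp, scale),
    residue_frames = fape(pred_coords, target_coords, residue_frames,
                          residue_frames, clamp, scale))
}

## ---- training --------------------------------------------------------------

# Static per-complex tensors reused at every step.
.loss_targets <- function(protein, ligand, target_coords, clamp, scale) {
  rf <- frames_to_arrays(build_residue_frames(protein))
  lt <- build_ligand_frames(ligand, coords = target_coords)
  lf <- frames_to_arrays(lt$frames)
  list(
    res_R = rf$R, res_t = rf$t,
    res_local = .local_coords(target_coords, rf),
    lig_local = .local_coords(target_coords, lf),
    target = target_coords)
}

# Loss for one forward pass (autodiff-aware). pose comes from
# structure_forward; tgt from .loss_targets. Ligand-frame alignment uses the
# predicted per-block frames with rotation gradients stopped.
.docking_loss <- function(pose, tgt, ligand, cfg) {
  lw <- cfg$loss
  nb <- length(pose$trajectory)
  per_block <- vector("list", nb)
  comp_final <- NULL
  for (b in seq_len(nb)) {
    tb <- pose$trajectory[[b]]
    Xv <- ad_val(tb)
    ligf <- build_ligand_frames(ligand, coords = Xv)$frames
    lfa <- frames_to_arrays(ligf)
    f_lig <- ad_fape(tb, lfa$R, tgt$lig_local, lw$clamp, lw$scale,
                     origin_idx = seq_len(nrow(Xv)))
    f_res <- ad_fape(tb, tgt$res_R, tgt$res_local, lw$clamp, lw$scale,
                     origin_const = tgt$res_t)
    comb <- ad_scale(ad_add(f_lig, f_res), 0.5)
    per_block[[b]] <- comb
    if (b == nb) comp_final <- list(lig = f_lig, res = f_res, comb = comb)
  }
  kab <- ad_kabsch_rmsd(pose$trajectory[[nb]], tgt$target)
  inter_mean <- per_block[[1]]
  if (nb > 1L) {
    for (b in 2:nb) inter_mean <- ad_add(inter_mean, per_block[[b]])
    inter_mean <- ad_scale(inter_mean, 1 / nb)
  }
  total <- ad_add(ad_add(ad_scale(comp_final$comb, lw$w_fape),
                         ad_scale(inter_mean, lw$w_intermediate)),
                  ad_scale(kab, lw$w_kabsch))
  list(total = total,
       breakdown = loss_breakdown(
         fape_ligand_frames = ad_val(comp_final$lig),
         fape_residue_frames = ad_val(comp_final$res),
         fape_intermediate = vapply(per_block, ad_val, numeric(1)),
         kabsch_rmsd = ad_val(kab),
         weights = lw))
}

#' Loss breakdown record
#'
#' @param fape_ligand_frames final-block ligand-frame FAPE component.
#' @param fape_residue_frames final-block residue-frame FAPE component.
#' @param fape_intermediate per-block combined FAPE (length = number of
#'   structure blocks).
#' @param kabsch_rmsd Kabsch RMSD of the final block (Angstrom).
#' @param weights loss weight list (`w_fape`, `w_intermediate`, `w_kabsch`).
#' @return A `loss_breakdown` list with `total` equal to
#'   `w_fape * (ligand + residue)/2 + w_intermediate * mean(intermediate) +
#'   w_kabsch * kabsch`.
#' @export
loss_breakdown <- function(fape_ligand_frames, fape_residue_frames,
                           fape_intermediate, kabsch_rmsd, weights) {
  total <- weights$w_fape * (fape_ligand_frames + fape_residue_frames) / 2 +
    weights$w_intermediate * mean(fape_intermediate) +
    weights$w_kabsch * kabsch_rmsd
  structure(list(fape_ligand_frames = fape_ligand_frames,
                 fape_residue_frames = fape_residue_frames,
                 fape_intermediate = fape_intermediate,
                 kabsch_rmsd = kabsch_rmsd,
                 total = total), class = "loss_breakdown")
}

# Adam optimizer over a parameter tree (in place on plain numeric values).
.adam_init <- function(params) {
  if (is.list(params)) return(lapply(params, .adam_init))
  list(m = params * 0, v = params * 0)
}

.adam_step <- function(params, grads, state, lr, b1, b2, eps, t) {
  if (is.list(params)) {
    out <- vector("list", length(params))
    names(out) <- names(params)
    st <- vector("list", length(params))
    names(st) <- names(params)
    for (k in seq_along(params)) {
      r <- .adam_step(params[[k]], grads[[k]], state[[k]], lr, b1, b2, eps, t)
      out[[k]] <- r$p; st[[k]] <- r$s
    }
    return(list(p = out, s = st))
  }
  m <- b1 * state$m + (1 - b1) * grads
  v <- b2 * state$v + (1 - b2) * grads^2
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  list(p = params - lr * mhat / (sqrt(vhat) + eps), s = list(m = m, v = v))
}

#' Train the docking model
#'
#' Full-graph gradient training with Adam on a list of complexes. Each
#' training example is a `list(protein = , ligand = , pose = )` with `pose`
#' the target ligand coordinates (canonical atom order). Deterministic
#' given the seed; aborts with a diagnostic if the loss becomes
#' non-finite.
#'
#' @param complexes list of training examples (fixture complexes work
#'   directly, see [make_complex()]).
#' @param config An [fd_config()] (use the `"tiny"` preset on CPU).
#' @param seed integer seed for initialization and example order.
#' @param steps number of optimizer steps (default from config).
#' @param lr learning rate (default from config).
#' @param params optional warm-start parameters.
#' @param verbose print progress every 50 steps.
#' @return `list(params, metrics, config)`; `metrics` is a data.frame with
#'   one row per step (step, loss components, total).
#' @export
fd_train <- function(complexes, config, seed = 1L, steps = NULL, lr = NULL,
                     params = NULL, verbose = FALSE) {
  steps <- steps %||% config$train$steps
  lr <- lr %||% config$train$lr
  tr <- config$train
  if (is.null(params)) params <- init_params(config, seed = seed)
  tgts <- lapply(complexes, function(cx) {
    .loss_targets(cx$protein, cx$ligand, cx$pose, config$loss$clamp,
                  config$loss$scale)
  })
  state <- .adam_init(params)
  metrics <- vector("list", steps)
  withr::with_seed(seed + 1L, {
    for (step in seq_len(steps)) {
      cx <- complexes[[(step - 1L) %% length(complexes) + 1L]]
      tgt <- tgts[[(step - 1L) %% length(complexes) + 1L]]
      nodes <- params_to_nodes(params)
      ad_tape_start()
      feats <- build_features(cx$protein, cx$ligand, nodes, config)
      feats <- trunk_forward(feats, nodes, config, training = TRUE)
      pose <- structure_forward(feats, cx$protein, cx$ligand, nodes, config)
      loss <- .docking_loss(pose, tgt, cx$ligand, config)
      lval <- ad_val(loss$total)
      if (!is.finite(lval)) {
        ad_tape_stop()
        rlang::abort(sprintf(
          "training diverged at step %d (last finite total %.4g at step %d)",
          step, if (step > 1) metrics[[step - 1L]]$total else NA, step - 1L),
          class = "fd_numeric_error")
      }
      ad_backward(loss$total)
      grads <- params_grads(nodes)
      ad_tape_stop()
      r <- .adam_step(params, grads, state, lr, tr$adam_beta1, tr$adam_beta2,
                      tr$adam_eps, step)
      params <- r$p; state <- r$s
      bd <- loss$breakdown
      metrics[[step]] <- data.frame(
        step = step, total = bd$total,
        fape_ligand_frames = bd$fape_ligand_frames,
        fape_residue_frames = bd$fape_residue_frames,
        fape_intermediate_mean = mean(bd$fape_intermediate),
        kabsch_rmsd = bd$kabsch_rmsd)
      if (verbose && step %% 50L == 0L) {
        message(sprintf("step %4d  total %.4f  kabsch %.3f", step,
                        bd$total, bd$kabsch_rmsd))
      }
    }
  })
  list(params = params, metrics = do.call(rbind, metrics), config = config)
}

#' Save / load a checkpoint (plain-text JSON)
#'
#' Weights, configuration and seed are stored as JSON with full numeric
#' precision.
#'
#' @param fit result of [fd_train()] (or `list(params, config)`).
#' @param path file path (`.json`).
#' @param seed seed to record.
#' @return `save_checkpoint` the path invisibly; `load_checkpoint` a
#'   `list(params, config, seed)`.
#' @export
save_checkpoint <- function(fit, path, seed = NULL) {
  obj <- list(config = unclass(fit$config), seed = seed,
              params = fit$params)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  cfg <- fd_config(preset = obj$config$preset %||% "default",
                   overrides = obj$config)
  params <- .restore_param_shapes(obj$params, init_params(cfg, seed = 1L))
  list(params = params, config = cfg, seed = obj$seed)
}

# JSON round-trips lose matrix dimensions in some layouts; restore them from
# a template tree.
.restore_param_shapes <- function(loaded, template) {
  if (is.list(template)) {
    out <- vector("list", length(template))
    names(out) <- names(template)
    for (k in seq_along(template)) {
      lk <- if (is.null(names(template))) loaded[[k]] else
        loaded[[names(template)[k]]]
      out[[k]] <- .restore_param_shapes(lk, template[[k]])
    }
    return(out)
  }
  if (is.matrix(template)) {
    if (is.matrix(loaded)) {
      matrix(as.numeric(loaded), nrow(template), ncol(template))
    } else {
      # list of row vectors: JSON stores matrices row-wise
      matrix(as.numeric(unlist(loaded)), nrow(template), ncol(template),
             byrow = TRUE)
    }
  } else {
    as.numeric(unlist(loaded))
  }
}
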