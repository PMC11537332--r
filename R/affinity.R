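# Binding-affinity head: a small MLP on the mean-pooled protein and ligand
# single representations, trained separately from the docking model with
# the embeddings frozen. Includes the virtual-screening driver and a
# one-sided rank-sum utility for binder/non-binder separation analyses.

#' Pool a single representation into molecule-level embeddings
#'
#' Arithmetic mean over protein rows and over ligand rows, separately.
#'
#' @param single (n_res + n_atoms) x C matrix.
#' @param mask_protein logical vector: TRUE for protein rows.
#' @return `list(protein = <length-C>, ligand = <length-C>)`.
#' @export
pool_embeddings <- function(single, mask_protein) {
  single <- as.matrix(single)
  if (!any(mask_protein) || all(mask_protein)) {
    rlang::abort("mask must contain both protein and ligand rows",
                 class = "fd_empty_error")
  }
  list(protein = colMeans(single[mask_protein, , drop = FALSE]),
       ligand = colMeans(single[!mask_protein, , drop = FALSE]))
}

#' Initialize an affinity head
#'
#' Two-layer perceptron: concatenated pooled protein + ligand embedding ->
#' hidden (ReLU) -> scalar on the pKd scale.
#'
#' @param c_s single-representation width (input is `2 * c_s`).
#' @param hidden hidden width (default 64).
#' @param seed integer seed.
#' @return Parameter list of class `affinity_head`.
#' @export
affinity_head <- function(c_s, hidden = 64L, seed = 1L) {
  withr::with_seed(seed, {
    structure(list(
      w1 = .mk_w(2L * c_s, hidden), b1 = rep(0, hidden),
      w2 = .mk_w(hidden, 1L), b2 = 0), class = "affinity_head")
  })
}

#' Predict binding affinity from pooled embeddings
#'
#' @param pooled `list(protein, ligand)` from [pool_embeddings()], or a
#'   numeric feature vector of length `2 * c_s`.
#' @param head An [affinity_head()].
#' @return Scalar predicted affinity (pKd scale).
#' @export
predict_affinity <- function(pooled, head) {
  x <- if (is.list(pooled)) c(pooled$protein, pooled$ligand) else as.numeric(pooled)
  h <- pmax(0, as.vector(x %*% head$w1) + head$b1)
  as.vector(h %*% head$w2) + head$b2
}

#' Train the affinity head on frozen embeddings
#'
#' Full-batch Adam on squared error. The docking model is not touched: the
#' embedding matrix is precomputed and frozen.
#'
#' @param features n x (2*c_s) matrix of concatenated pooled embeddings.
#' @param labels length-n affinity labels (pKd scale).
#' @param hidden hidden width.
#' @param steps optimizer steps (default 1500).
#' @param lr learning rate.
#' @param seed integer seed.
#' @return A trained [affinity_head()].
#' @export
train_affinity_head <- function(features, labels, hidden = 64L, steps = 1500L,
                                lr = 5e-3, seed = 1L) {
  features <- as.matrix(features)
  labels <- matrix(as.numeric(labels), ncol = 1)
  mu <- colMeans(features); sdv <- pmax(apply(features, 2, stats::sd), 1e-8)
  X <- sweep(sweep(features, 2, mu), 2, sdv, "/")
  head <- affinity_head(ncol(features) %/% 2L, hidden = hidden, seed = seed)
  params <- list(w1 = head$w1, b1 = head$b1, w2 = head$w2,
                 b2 = matrix(head$b2, 1, 1))
  state <- .adam_init(params)
  for (step in seq_len(steps)) {
    nodes <- params_to_nodes(params)
    ad_tape_start(256L)
    hlin <- ad_linear(X, nodes$w1, nodes$b1)
    hact <- ad_relu(hlin)
    pred <- ad_addrow(ad_matmul(hact, nodes$w2), nodes$b2)
    err <- ad_sub(pred, labels)
    loss <- ad_mean(ad_mul(err, err))
    ad_backward(loss)
    grads <- params_grads(nodes)
    ad_tape_stop()
    r <- .adam_step(params, grads, state, lr, 0.9, 0.999, 1e-8, step)
    params <- r$p; state <- r$s
  }
  structure(list(w1 = params$w1, b1 = as.numeric(params$b1),
                 w2 = params$w2, b2 = as.numeric(params$b2),
                 norm_mu = mu, norm_sd = sdv), class = "affinity_head")
}

#' Pooled complex embeddings for a protein-ligand pair
#'
#' Runs the model in evaluation mode and returns the concatenated
#' mean-pooled protein and ligand single-representation rows. With
#' `stage = "trunk"` the single representation is taken after the trunk
#' (the stage the interpretability pipeline reads, and the default input
#' of the affinity head); with `stage = "final"` after the structure
#' module.
#'
#' @param protein A [protein_structure()].
#' @param ligand A [ligand_graph()].
#' @param params model parameters.
#' @param config An [fd_config()].
#' @param stage `"trunk"` or `"final"`.
#' @return `list(protein = , ligand = , features = <concatenation>)`.
#' @export
complex_embeddings <- function(protein, ligand, params, config,
                               stage = c("trunk", "final")) {
  stage <- match.arg(stage)
  if (stage == "final") {
    pose <- dock(protein, ligand, params, config)
    p <- pool_embeddings(pose$single_final, pose$mask_protein)
  } else {
    feats <- build_features(protein, ligand, params, config)
    feats <- trunk_forward(feats, params, config)
    p <- pool_embeddings(ad_val(feats$single), feats$mask_protein)
  }
  list(protein = p$protein, ligand = p$ligand,
       features = c(p$protein, p$ligand))
}

#' Affinity feature vector from a docked pose
#'
#' Concatenated mean-pooled protein and ligand rows of the final single
#' representation, with the head's stored normalization applied at
#' prediction time.
#'
#' @param pose A `pose_result` from [dock()].
#' @return Numeric feature vector.
#' @export
affinity_features <- function(pose) {
  p <- pool_embeddings(pose$single_final, pose$mask_protein)
  c(p$protein, p$ligand)
}

#' Predict affinity for a docked pose
#' @param pose A `pose_result`.
#' @param head A trained [affinity_head()].
#' @return Scalar predicted affinity.
#' @export
predict_pose_affinity <- function(pose, head) {
  x <- affinity_features(pose)
  if (!is.null(head$norm_mu)) {
    x <- (x - head$norm_mu) / head$norm_sd
  }
  predict_affinity(x, head)
}

#' Virtual screen of a ligand library against one target
#'
#' Docks every ligand, predicts its affinity, and returns the table ranked
#' by predicted affinity (best first). Per-ligand failures are recorded in
#' the `status` column and do not abort the screen.
#'
#' @param protein A [protein_structure()].
#' @param ligands named list of [ligand_graph()].
#' @param params docking model parameters.
#' @param config An [fd_config()].
#' @param head A trained [affinity_head()].
#' @param out_dir optional directory for pose SDF files.
#' @return data.frame (id, affinity, pose_path, status), ranked.
#' @export
screen <- function(protein, ligands, params, config, head, out_dir = NULL) {
  ids <- names(ligands) %||% sprintf("lig_%03d", seq_along(ligands))
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(ligands), function(i) {
    r <- tryCatch({
      pose <- dock(protein, ligands[[i]], params, config)
      aff <- predict_pose_affinity(pose, head)
      path <- NA_character_
      if (!is.null(out_dir)) {
        path <- file.path(out_dir, paste0(ids[i], "_pose.sdf"))
        write_pose(ligands[[i]], pose$coords, path,
                   provenance = list(config_hash = pose$meta$config_hash,
                                     predicted_affinity = aff))
      }
      data.frame(id = ids[i], affinity = aff, pose_path = path, status = "ok")
    }, error = function(e) {
      data.frame(id = ids[i], affinity = NA_real_, pose_path = NA_character_,
                 status = paste0("error: ", conditionMessage(e)))
    })
    r
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(id = character(0), affinity = numeric(0),
                      pose_path = character(0), status = character(0))
  }
  out[order(-out$affinity, na.last = TRUE), , drop = FALSE]
}

#' One-sided Wilcoxon rank-sum test between two score groups
#'
#' Utility for binder/non-binder separation: tests whether scores in `x`
#' are stochastically greater than scores in `y` (exact p-value when both
#' groups are small and tie-free).
#'
#' @param x,y numeric score vectors.
#' @param alternative `"greater"` (default), `"less"`, or `"two.sided"`.
#' @return `list(statistic = <rank-sum W>, p.value = )`.
#' @export
rank_sum_test <- function(x, y, alternative = "greater") {
  wt <- stats::wilcox.test(x, y, alternative = alternative,
                           exact = (length(x) <= 50 && length(y) <= 50 &&
                                      !anyDuplicated(c(x, y))))
  list(statistic = unname(wt$statistic), p.value = wt$p.value)
}
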