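# The docking network: an attention trunk over the single/pair
# representations (row-wise gated attention with pair bias, outer-product
# update into the pair, triangle multiplicative updates and triangle
# attention; no column-wise attention because there is no alignment axis),
# followed by an iterative structure module that moves ligand atom frames
# with gated invariant point attention and ligand-to-protein cross
# attention. Protein frames are never updated.

.tperm <- function(N) as.vector(t(matrix(seq_len(N * N), N, N)))

## ---- parameters ------------------------------------------------------------

.mk_w <- function(fin, fout, zero = FALSE) {
  if (zero) matrix(0, fin, fout) else
    matrix(stats::rnorm(fin * fout, sd = 1 / sqrt(fin)), fin, fout)
}

.mk_ln <- function(c) list(g = rep(1, c), b = rep(0, c))

.mk_trans <- function(c, mult) {
  ln <- .mk_ln(c)
  list(ln_g = ln$g, ln_b = ln$b,
       w1 = .mk_w(c, mult * c), b1 = rep(0, mult * c),
       w2 = .mk_w(mult * c, c, zero = TRUE), b2 = rep(0, c))
}

.mk_attn <- function(c_s, c_z, h) {
  dh <- c_s %/% h
  ln <- .mk_ln(c_s); lnz <- .mk_ln(c_z)
  list(ln_g = ln$g, ln_b = ln$b, lnz_g = lnz$g, lnz_b = lnz$b,
       wq = .mk_w(c_s, h * dh), wk = .mk_w(c_s, h * dh), wv = .mk_w(c_s, h * dh),
       wb = .mk_w(c_z, h), wg = .mk_w(c_s, h * dh, zero = TRUE),
       bg = rep(1, h * dh), wo = .mk_w(h * dh, c_s, zero = TRUE))
}

.mk_tri_mul <- function(c_z) {
  ln <- .mk_ln(c_z); lno <- .mk_ln(c_z)
  list(ln_g = ln$g, ln_b = ln$b,
       wa = .mk_w(c_z, c_z), wag = .mk_w(c_z, c_z, zero = TRUE), bag = rep(1, c_z),
       wb = .mk_w(c_z, c_z), wbg = .mk_w(c_z, c_z, zero = TRUE), bbg = rep(1, c_z),
       lno_g = lno$g, lno_b = lno$b,
       wg = .mk_w(c_z, c_z, zero = TRUE), bg = rep(1, c_z),
       wo = .mk_w(c_z, c_z, zero = TRUE))
}

.mk_tri_attn <- function(c_z, h) {
  dz <- max(1L, c_z %/% h)
  ln <- .mk_ln(c_z)
  list(ln_g = ln$g, ln_b = ln$b,
       wq = .mk_w(c_z, h * dz), wk = .mk_w(c_z, h * dz), wv = .mk_w(c_z, h * dz),
       wb = .mk_w(c_z, h),
       wg = .mk_w(c_z, h * dz, zero = TRUE), bg = rep(1, h * dz),
       wo = .mk_w(h * dz, c_z, zero = TRUE))
}

#' Initialize model parameters
#'
#' Weights use 1/sqrt(fan-in) normal initialization; every residual
#' branch's output projection is zero-initialized so the untrained network
#' is the identity on its representations and leaves the initial ligand
#' placement unchanged.
#'
#' @param config An [fd_config()].
#' @param seed integer seed.
#' @return Nested list of parameter arrays.
#' @export
init_params <- function(config, seed = 1L) {
  withr::with_seed(seed, {
    m <- config$model
    c_s <- m$c_s; c_z <- m$c_z
    d_lig <- ncol(ligand_atom_features(
      ligand_graph("C", matrix(integer(0), 0, 3), canonicalize = FALSE),
      config))
    d_prot <- 22L
    fz <- config$featurize
    d_pp <- fz$rbf_bins + 2L * fz$relpos_clip + 1L
    d_ll <- fz$rbf_bins + 1L + 5L
    embed <- list(
      w_protein = .mk_w(d_prot, c_s), b_protein = rep(0, c_s),
      w_ligand = .mk_w(d_lig, c_s), b_ligand = rep(0, c_s),
      w_pair_row = .mk_w(c_s, c_z), w_pair_col = .mk_w(c_s, c_z),
      w_pair_protein = .mk_w(d_pp, c_z), w_pair_ligand = .mk_w(d_ll, c_z))
    tm <- m$trunk
    trunk <- lapply(seq_len(tm$n_blocks), function(b) {
      k <- tm$opm_hidden
      opm_ln <- .mk_ln(c_s)
      list(
        attn = .mk_attn(c_s, c_z, tm$heads),
        trans = .mk_trans(c_s, tm$transition_mult),
        opm = list(ln_g = opm_ln$g, ln_b = opm_ln$b,
                   wu = .mk_w(c_s, k), wv = .mk_w(c_s, k),
                   wo = .mk_w(k * k, c_z, zero = TRUE)),
        tri_out = .mk_tri_mul(c_z),
        tri_in = .mk_tri_mul(c_z),
        tas = .mk_tri_attn(c_z, tm$heads),
        tae = .mk_tri_attn(c_z, tm$heads),
        ptrans = .mk_trans(c_z, tm$transition_mult))
    })
    sm <- m$structure
    h <- sm$heads; dh <- sm$d_head
    npq <- sm$points_q; npv <- sm$points_v
    ipa_out_w <- h * dh + h * c_z + h * npv * 3L + h * npv
    ln1 <- .mk_ln(c_s); lnz <- .mk_ln(c_z)
    lnq <- .mk_ln(c_s); lnkv <- .mk_ln(c_s); lnu <- .mk_ln(c_s)
    structure_p <- list(
      ipa = list(ln_g = ln1$g, ln_b = ln1$b, lnz_g = lnz$g, lnz_b = lnz$b,
                 wq = .mk_w(c_s, h * dh), wk = .mk_w(c_s, h * dh),
                 wv = .mk_w(c_s, h * dh),
                 wqp = .mk_w(c_s, h * npq * 3L), wkp = .mk_w(c_s, h * npq * 3L),
                 wvp = .mk_w(c_s, h * npv * 3L),
                 wb = .mk_w(c_z, h),
                 gamma_raw = rep(0.5413, h),     # softplus^-1(1)
                 wg = .mk_w(c_s, ipa_out_w, zero = TRUE), bg = rep(1, ipa_out_w),
                 wo = .mk_w(ipa_out_w, c_s, zero = TRUE)),
      trans = .mk_trans(c_s, 2L),
      cross = list(lnq_g = lnq$g, lnq_b = lnq$b, lnkv_g = lnkv$g, lnkv_b = lnkv$b,
                   wq = .mk_w(c_s, h * dh), wk = .mk_w(c_s, h * dh),
                   wv = .mk_w(c_s, h * dh),
                   wo = .mk_w(h * dh, c_s, zero = TRUE)),
      update = list(ln_g = lnu$g, ln_b = lnu$b,
                    w = .mk_w(c_s, 6L, zero = TRUE), b = rep(0, 6L)))
    list(embed = embed, trunk = trunk, structure = structure_p)
  })
}

#' Perturb zero-initialized output layers
#'
#' Replaces every all-zero weight matrix with a small random draw, so an
#' untrained network actually moves the ligand. Used by the invariance and
#' equivariance checks, which would otherwise exercise only the identity
#' network.
#'
#' @param params parameter tree from [init_params()].
#' @param seed integer seed.
#' @param sd normal standard deviation for the replacement weights.
#' @return The perturbed parameter tree.
#' @export
wake_params <- function(params, seed = 1L, sd = 0.05) {
  withr::with_seed(seed, {
    wake <- function(p) {
      if (is.list(p)) return(lapply(p, wake))
      if (is.matrix(p) && all(p == 0)) {
        return(matrix(stats::rnorm(length(p), sd = sd), nrow(p)))
      }
      p
    }
    wake(params)
  })
}

# Wrap every numeric leaf of a parameter tree in an autodiff leaf node.
params_to_nodes <- function(params) {
  if (is.list(params)) return(lapply(params, params_to_nodes))
  ad_leaf(params)
}

# Extract values / gradients back out of a node tree.
params_values <- function(nodes) {
  if (is.list(nodes)) return(lapply(nodes, params_values))
  nodes$val
}

params_grads <- function(nodes) {
  if (is.list(nodes)) return(lapply(nodes, params_grads))
  if (is.null(nodes$grad)) nodes$val * 0 else nodes$grad
}

## ---- trunk -----------------------------------------------------------------

.transition <- function(x, p) {
  xn <- ad_layernorm(x, p$ln_g, p$ln_b)
  ad_add(x, ad_linear(ad_relu(ad_linear(xn, p$w1, p$b1)), p$w2, p$b2))
}

.tri_mul_block <- function(z, p, N, mode) {
  zn <- ad_layernorm(z, p$ln_g, p$ln_b)
  a <- ad_mul(ad_sigmoid(ad_linear(zn, p$wag, p$bag)), ad_linear(zn, p$wa))
  b <- ad_mul(ad_sigmoid(ad_linear(zn, p$wbg, p$bbg)), ad_linear(zn, p$wb))
  tm <- ad_tri_mul(a, b, N, mode)
  tn <- ad_layernorm(tm, p$lno_g, p$lno_b)
  g <- ad_sigmoid(ad_linear(zn, p$wg, p$bg))
  ad_add(z, ad_mul(g, ad_linear(tn, p$wo)))
}

.tri_attn_block <- function(z, p, N, h, ending = FALSE) {
  zin <- if (ending) ad_permute_rows(z, .tperm(N)) else z
  zn <- ad_layernorm(zin, p$ln_g, p$ln_b)
  att <- ad_tri_attn(ad_linear(zn, p$wq), ad_linear(zn, p$wk),
                     ad_linear(zn, p$wv), ad_linear(zn, p$wb), h, N)
  g <- ad_sigmoid(ad_linear(zn, p$wg, p$bg))
  delta <- ad_linear(ad_mul(att, g), p$wo)
  if (ending) delta <- ad_permute_rows(delta, .tperm(N))
  ad_add(z, delta)
}

.dropout <- function(x, rate, training) {
  if (!training || rate <= 0) return(x)
  xv <- ad_val(x)
  mask <- (matrix(stats::runif(length(xv)), nrow(xv)) > rate) / (1 - rate)
  ad_mul(x, mask)
}

#' Run the trunk over complex features
#'
#' Each block applies row-wise gated self-attention with pair bias, a single
#' transition, an outer-product update from the single into the pair,
#' triangle multiplicative updates (outgoing and incoming), triangle
#' attention (starting and ending node), and a pair transition. Shapes are
#' preserved; eval mode is deterministic.
#'
#' @param features A `complex_features` list from [build_features()].
#' @param params Model parameters ([init_params()]), plain or node-wrapped.
#' @param config An [fd_config()].
#' @param training apply dropout (training mode only).
#' @return The features with updated `single` and `pair`.
#' @export
trunk_forward <- function(features, params, config, training = FALSE) {
  N <- features$N
  h <- config$model$trunk$heads
  rate <- config$model$trunk$dropout
  x <- features$single
  z <- features$pair
  for (blk in params$trunk) {
    p <- blk$attn
    xn <- ad_layernorm(x, p$ln_g, p$ln_b)
    zn <- ad_layernorm(z, p$lnz_g, p$lnz_b)
    att <- ad_mha(ad_linear(xn, p$wq), ad_linear(xn, p$wk),
                  ad_linear(xn, p$wv), h, bias = ad_linear(zn, p$wb))
    g <- ad_sigmoid(ad_linear(xn, p$wg, p$bg))
    x <- ad_add(x, .dropout(ad_linear(ad_mul(att, g), p$wo), rate, training))
    x <- .transition(x, blk$trans)
    po <- blk$opm
    xo <- ad_layernorm(x, po$ln_g, po$ln_b)
    z <- ad_add(z, ad_linear(ad_outer_pair(ad_linear(xo, po$wu),
                                           ad_linear(xo, po$wv)), po$wo))
    z <- .tri_mul_block(z, blk$tri_out, N, "out")
    z <- .tri_mul_block(z, blk$tri_in, N, "in")
    z <- .tri_attn_block(z, blk$tas, N, h, ending = FALSE)
    z <- .tri_attn_block(z, blk$tae, N, h, ending = TRUE)
    z <- .transition(z, blk$ptrans)
  }
  xv <- ad_val(x); zv <- ad_val(z)
  if (!all(is.finite(xv)) || !all(is.finite(zv))) {
    rlang::abort("non-finite activations in trunk", class = "fd_numeric_error")
  }
  features$single <- x
  features$pair <- z
  features
}

## ---- structure module ------------------------------------------------------

#' Gated invariant point attention layer
#'
#' One IPA layer over all rows: scalar queries/keys, pair bias, and point
#' attention computed in the per-row local frames, followed by a learned
#' sigmoid gate and an output projection with residual connection. Output
#' is invariant under a global rigid motion of all frames.
#'
#' @param single (N x c_s) single representation (matrix or node).
#' @param pair ((N*N) x c_z) pair representation, pair-flat.
#' @param frames list of N [rigid_transform()] (or `list(R = 3x3xN, t = Nx3)`),
#'   one per row; translations may be an autodiff node.
#' @param params the `structure` parameter group from [init_params()].
#' @param config An [fd_config()].
#' @return Updated single representation (same shape).
#' @export
gated_ipa <- function(single, pair, frames, params, config) {
  p <- params$ipa
  sm <- config$model$structure
  if (!is.list(frames) || is.null(frames$R)) frames <- frames_to_arrays(frames)
  xn <- ad_layernorm(single, p$ln_g, p$ln_b)
  zn <- ad_layernorm(pair, p$lnz_g, p$lnz_b)
  core <- ad_ipa_core(
    q = ad_linear(xn, p$wq), k = ad_linear(xn, p$wk), v = ad_linear(xn, p$wv),
    qp = ad_linear(xn, p$wqp), kp = ad_linear(xn, p$wkp),
    vp = ad_linear(xn, p$wvp),
    bias = ad_linear(zn, p$wb), z = zn, gamma_raw = p$gamma_raw,
    R = frames$R, t = frames$t, h = sm$heads)
  g <- ad_sigmoid(ad_linear(xn, p$wg, p$bg))
  ad_add(single, ad_linear(ad_mul(core, g), p$wo))
}

#' Initial pose state for the structure module
#'
#' Ligand frames are built from the initial conformer placement; protein
#' frames from the backbone. Protein frames are constants for the whole
#' forward pass.
#'
#' @param features A `complex_features` list (after [trunk_forward()]).
#' @param protein A [protein_structure()].
#' @param ligand A [ligand_graph()].
#' @param init_coords n_atoms x 3 initial ligand coordinates; default places
#'   the conformer centroid at the protein C-alpha centroid (blind docking
#'   needs a canonical start).
#' @return A `pose_state` list.
#' @export
init_pose_state <- function(features, protein, ligand, init_coords = NULL) {
  if (is.null(init_coords)) {
    com <- colMeans(protein$ca)
    init_coords <- sweep(ligand$coords, 2, colMeans(ligand$coords)) +
      matrix(com, n_atoms(ligand), 3, byrow = TRUE)
  }
  pf <- frames_to_arrays(build_residue_frames(protein))
  lf <- frames_to_arrays(build_ligand_frames(ligand, coords = init_coords)$frames)
  structure(list(
    prot_R = pf$R, prot_t = pf$t,
    lig_R = lf$R, lig_t = lf$t,
    single = features$single,
    n_protein = features$n_protein, n_ligand = features$n_ligand,
    trajectory = list()), class = "pose_state")
}

#' Cross-attention coordinate update
#'
#' Ligand rows attend over protein rows; the attended ligand representation
#' produces one quaternion + translation update per atom, applied to the
#' ligand frames (protein frames untouched). The new ligand coordinates are
#' appended to the trajectory.
#'
#' @param pose A `pose_state`.
#' @param params the `structure` parameter group.
#' @param config An [fd_config()].
#' @return The updated `pose_state`.
#' @export
coordinate_update <- function(pose, params, config) {
  sm <- config$model$structure
  p <- params$cross
  np <- pose$n_protein; nl <- pose$n_ligand
  lig_rows <- np + seq_len(nl)
  sl <- ad_slice_rows(pose$single, lig_rows)
  sp <- ad_slice_rows(pose$single, seq_len(np))
  qn <- ad_layernorm(sl, p$lnq_g, p$lnq_b)
  kn <- ad_layernorm(sp, p$lnkv_g, p$lnkv_b)
  catt <- ad_mha(ad_linear(qn, p$wq), ad_linear(kn, p$wk),
                 ad_linear(kn, p$wv), sm$heads)
  pose$single <- ad_add_rows_subset(pose$single, lig_rows,
                                    ad_linear(catt, p$wo))
  pu <- params$update
  upd_in <- ad_slice_rows(pose$single, lig_rows)
  raw <- ad_linear(ad_layernorm(upd_in, pu$ln_g, pu$ln_b), pu$w, pu$b)
  fu <- ad_frame_update(pose$lig_t, pose$lig_R, raw, sm$position_scale)
  pose$lig_t <- fu$t
  pose$lig_R <- fu$R
  pose$trajectory[[length(pose$trajectory) + 1L]] <- fu$t
  pose
}

# One full structure-module block: gated IPA + transition + coordinate update.
.structure_block <- function(pose, zn_cache, params, config) {
  R_all <- array(0, c(3, 3, pose$n_protein + pose$n_ligand))
  R_all[, , seq_len(pose$n_protein)] <- pose$prot_R
  R_all[, , pose$n_protein + seq_len(pose$n_ligand)] <- pose$lig_R
  t_all <- ad_rbind2(pose$prot_t, pose$lig_t)
  p <- params$ipa
  sm <- config$model$structure
  xn <- ad_layernorm(pose$single, p$ln_g, p$ln_b)
  core <- ad_ipa_core(
    q = ad_linear(xn, p$wq), k = ad_linear(xn, p$wk), v = ad_linear(xn, p$wv),
    qp = ad_linear(xn, p$wqp), kp = ad_linear(xn, p$wkp),
    vp = ad_linear(xn, p$wvp),
    bias = zn_cache$bias, z = zn_cache$zn, gamma_raw = p$gamma_raw,
    R = R_all, t = t_all, h = sm$heads)
  g <- ad_sigmoid(ad_linear(xn, p$wg, p$bg))
  pose$single <- ad_add(pose$single, ad_linear(ad_mul(core, g), p$wo))
  pose$single <- .transition(pose$single, params$trans)
  coordinate_update(pose, params, config)
}

#' Run the structure module
#'
#' Iterates the shared-weight structure block `n_blocks` times, recording
#' the ligand coordinates after every block. Protein frames are bitwise
#' constant throughout.
#'
#' @inheritParams init_pose_state
#' @param params model parameters.
#' @param config An [fd_config()].
#' @return The final `pose_state` (trajectory has one entry per block).
#' @export
structure_forward <- function(features, protein, ligand, params, config,
                              init_coords = NULL) {
  pose <- init_pose_state(features, protein, ligand, init_coords)
  p <- params$structure$ipa
  zn <- ad_layernorm(features$pair, p$lnz_g, p$lnz_b)
  zn_cache <- list(zn = zn, bias = ad_linear(zn, p$wb))
  for (b in seq_len(config$model$structure$n_blocks)) {
    pose <- .structure_block(pose, zn_cache, params$structure, config)
  }
  pose
}

#' Dock a ligand into a protein
#'
#' Runs featurization, the trunk and the structure module in evaluation
#' mode and returns the predicted pose with its per-block trajectory and
#' the single representations used by the affinity and interpretability
#' pipelines.
#'
#' @param protein A [protein_structure()].
#' @param ligand A [ligand_graph()] with conformer.
#' @param params model parameters ([init_params()] or a trained checkpoint).
#' @param config An [fd_config()].
#' @param init_coords optional initial ligand placement (n x 3).
#' @return A `pose_result`: `coords` (n_atoms x 3), `trajectory` (list, one
#'   per structure block), `single_final`, `single_trunk`, `mask_protein`,
#'   `meta` (config hash, runtime seconds).
#' @export
dock <- function(protein, ligand, params, config, init_coords = NULL) {
  t0 <- proc.time()[["elapsed"]]
  feats <- build_features(protein, ligand, params, config)
  feats <- trunk_forward(feats, params, config, training = FALSE)
  single_trunk <- ad_val(feats$single)
  pose <- structure_forward(feats, protein, ligand, params, config,
                            init_coords = init_coords)
  coords <- ad_val(pose$lig_t)
  if (!all(is.finite(coords))) {
    rlang::abort("non-finite coordinates from structure module",
                 class = "fd_numeric_error")
  }
  structure(list(
    coords = coords,
    trajectory = lapply(pose$trajectory, ad_val),
    single_final = ad_val(pose$single),
    single_trunk = single_trunk,
    mask_protein = feats$mask_protein,
    ligand = ligand, protein = protein,
    meta = list(config_hash = config_hash(config),
                runtime_s = proc.time()[["elapsed"]] - t0)),
    class = "pose_result")
}

#' @export
print.pose_result <- function(x, ...) {
  cat(sprintf("<pose_result> %d ligand atoms, %d structure blocks, %.2fs\n",
              nrow(x$coords), length(x$trajectory), x$meta$runtime_s))
  invisible(x)
}
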