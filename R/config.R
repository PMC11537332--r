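# Run configuration: model sizes, featurization settings, loss weights,
# seeds. Two presets: "default" is the shipping architecture (12 trunk
# blocks, 8 structure blocks, 64 ligand single channels); "tiny" is the
# desk-scale configuration used throughout the test suite (2 + 2 blocks,
# width 32).

.fd_merge <- function(base, override) {
  for (k in names(override)) {
    if (is.list(override[[k]]) && is.list(base[[k]])) {
      base[[k]] <- .fd_merge(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Build a run configuration
#'
#' @param preset `"default"` (shipping sizes: 12 trunk blocks, 8 structure
#'   blocks, 64 single channels) or `"tiny"` (2 + 2 blocks, width 32; used
#'   by the tests and the CPU training harness).
#' @param overrides nested list merged over the preset.
#' @return A nested configuration list of class `fd_config`.
#' @export
fd_config <- function(preset = c("default", "tiny"), overrides = list()) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    seed = 1L,
    conformer_seed = 2024L,
    model = list(
      c_s = 64L, c_z = 32L,
      trunk = list(n_blocks = 12L, heads = 8L, dropout = 0.15,
                   transition_mult = 2L, opm_hidden = 8L),
      structure = list(n_blocks = 8L, heads = 4L, d_head = 16L,
                       points_q = 4L, points_v = 8L,
                       position_scale = 10,
                       frame_mode = "lowest_index"),
      init_scale = 0.2
    ),
    featurize = list(rbf_bins = 16L, rbf_min = 0, rbf_max = 20,
                     relpos_clip = 32L, max_lig_idx = 32L),
    loss = list(clamp = 10, scale = 10,
                w_fape = 1.0, w_intermediate = 0.5, w_kabsch = 0.5),
    train = list(lr = 1e-3, steps = 500L,
                 adam_beta1 = 0.9, adam_beta2 = 0.999, adam_eps = 1e-8)
  )
  if (preset == "tiny") {
    cfg <- .fd_merge(cfg, list(
      model = list(c_s = 32L, c_z = 16L,
                   trunk = list(n_blocks = 2L, heads = 4L, dropout = 0),
                   structure = list(n_blocks = 2L, heads = 4L, d_head = 8L,
                                    points_q = 4L, points_v = 4L))
    ))
  }
  cfg <- .fd_merge(cfg, overrides)
  if (!identical(cfg$model$structure$frame_mode, "lowest_index")) {
    if (identical(cfg$model$structure$frame_mode, "nearest_atoms")) {
      stop("frame_mode 'nearest_atoms' (frames from the two spatially ",
           "closest atoms) is a recognized but unimplemented variant")
    }
    stop("unknown frame_mode: ", cfg$model$structure$frame_mode)
  }
  class(cfg) <- c("fd_config", "list")
  cfg
}

#' Save / load a configuration as YAML
#' @param cfg An [fd_config()] list.
#' @param path file path.
#' @return `save_config` returns the path invisibly; `load_config` returns
#'   the configuration.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  fd_config(preset = cfg$preset %||% "default", overrides = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stable hash of a configuration (provenance tag in output artifacts)
#' @param cfg An [fd_config()] list.
#' @return A character md5 hash.
#' @export
config_hash <- function(cfg) rlang::hash(unclass(cfg))
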