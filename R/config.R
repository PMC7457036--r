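#' Load a run configuration
#'
#' Reads a YAML configuration with named blocks \code{chambers},
#' \code{circulation}, \code{imp}, \code{schedule}, \code{trees},
#' \code{init}, \code{solver}; missing blocks and fields are filled with
#' the packaged defaults (the fixed elastance constants, IMP weights
#' 0.8/5/20, heart rate 100/min).  An empty file yields the full default
#' control configuration.  Every block is validated through its module's
#' constructor before a model is assembled.
#'
#' @param path path to a YAML file, or \code{NULL} for pure defaults.
#' @return A \code{\link{corosim_model}}.
#' @export
load_config <- function(path = NULL) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg)) cfg <- list()
  }
  ch <- cfg$chambers
  lv_defaults <- list(Ees = 3.18, V0 = -15, A = 12.8, B = 0.015,
                      Tmax = 0.2, tau = 0.04)
  la_defaults <- list(Ees = 1.50, V0 = 5, A = 0.044, B = 0.049,
                      Tmax = 0.125, tau = 0.08)
  lv <- utils::modifyList(lv_defaults, ch$lv %||% list())
  la <- utils::modifyList(la_defaults, ch$la %||% list())
  lv_lad <- do.call(chamber_params, lv)
  lv_lcx <- do.call(chamber_params,
                    utils::modifyList(lv, list(Ees = ch$Ees_lcx %||% lv$Ees)))
  sc <- cfg$schedule %||% list()
  sched <- activation_schedule(
    T = sc$T %||% 60 / (sc$heart_rate %||% 100),
    dt_lcx = sc$dt_lcx %||% 0,
    dt_bar = sc$dt_bar %||% 0,
    SDI = sc$SDI,
    la_offset = sc$la_offset %||% 0.105)
  circ <- do.call(circ_params, cfg$circulation %||% list())
  impp <- do.call(imp_params, cfg$imp %||% list())
  tr <- cfg$trees %||% list()
  tree_for <- function(side, default_seed) {
    x <- tr[[side]]
    if (is.null(x)) return(generate_tree(morphometry_spec(seed = default_seed)))
    if (is.character(x)) return(read_tree(x))
    generate_tree(do.call(morphometry_spec, x))
  }
  init_defaults <- list(V_la = 110, V_lv = 50, V_art = 90, V_ven = 250)
  corosim_model(
    lv_law = cfg$lv_law %||% "shared",
    ve_cross = cfg$ve_cross %||% FALSE,
    lv_lad = lv_lad, lv_lcx = lv_lcx,
    la = do.call(chamber_params, la),
    F = cfg$chambers$F %||% 0.5,
    circ = circ, imp = impp, sched = sched,
    tree_lad = tree_for("lad", 20L), tree_lcx = tree_for("lcx", 21L),
    mu = blood_viscosity(cfg$viscosity_cP %||% 3.5),
    init = utils::modifyList(init_defaults, cfg$init %||% list()),
    solver = cfg$solver %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the packaged fixtures to a directory
#'
#' Writes the default run configuration, the three-animal measurement
#' table and the two generated coronary tree files (fixed seeds, so the
#' files are byte-identical across calls).
#'
#' @param out_dir writable directory (created if needed).
#' @param seed_lad,seed_lcx tree generation seeds.
#' @return Invisibly, the written file paths.
#' @export
make_fixtures <- function(out_dir, seed_lad = 20L, seed_lcx = 21L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "default_config.yaml")
  file.copy(system.file("extdata", "default_config.yaml",
                        package = "corosim", mustWork = TRUE),
            cfg_path, overwrite = TRUE)
  tgt_path <- file.path(out_dir, "swine_targets.tsv")
  file.copy(system.file("extdata", "swine_targets.tsv",
                        package = "corosim", mustWork = TRUE),
            tgt_path, overwrite = TRUE)
  lad_path <- file.path(out_dir, "tree_lad.tsv")
  lcx_path <- file.path(out_dir, "tree_lcx.tsv")
  write_tree(generate_tree(morphometry_spec(seed = seed_lad)), lad_path)
  write_tree(generate_tree(morphometry_spec(seed = seed_lcx)), lcx_path)
  invisible(c(cfg_path, tgt_path, lad_path, lcx_path))
}

#' Write simulation waveforms to a delimited text file
#'
#' Tab-delimited with a header line; time in seconds, pressures in mmHg,
#' volumes in ml, flows in ml/s.  Reading the file back reproduces the
#' table at the written precision.
#'
#' @param waveforms data frame (e.g. \code{run$waveforms}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_waveforms <- function(waveforms, path) {
  if (!is.data.frame(waveforms))
    stop("'waveforms' must be a data frame", call. = FALSE)
  if (nrow(waveforms) > 0 &&
      length(unique(vapply(waveforms, length, 1L))) != 1L)
    stop("waveform columns have unequal lengths", call. = FALSE)
  utils::write.table(waveforms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
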