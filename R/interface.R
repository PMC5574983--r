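#' Read a run configuration
#'
#' Reads a flat key-value configuration (YAML or JSON, decided by the file
#' extension) holding the model parameters (`a1`, `a2`, `b1`, `b2`, `k1`,
#' `k2`, `theta`, `n`), optionally a noise block (`D`, `seed`) and run
#' settings (`dt`, `t_end`, ...).  Missing kinetic constants other than the
#' self-activation rates are filled with the defaults `k1 = k2 = 1`,
#' `theta = 0.5`, `n = 4`, `b1 = 0.2`, `b2 = 1`; `a1` and `a2` must be
#' given.  Unknown keys are rejected.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return a list with elements `params` (a [model_params]), `D`, `seed`,
#'   and `settings` (any further keys from the recognised set).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  par_keys <- c("a1", "a2", "b1", "b2", "k1", "k2", "theta", "n")
  run_keys <- c("D", "seed", "dt", "t_end", "burn_in", "n_replicates",
                "resolution", "out")
  unknown <- setdiff(names(raw), c(par_keys, run_keys))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!all(c("a1", "a2") %in% names(raw)))
    stop("config must set the self-activation rates a1 and a2",
         call. = FALSE)
  defaults <- list(b1 = 0.2, b2 = 1.0, k1 = 1.0, k2 = 1.0, theta = 0.5,
                   n = 4)
  pars <- utils::modifyList(defaults, raw[intersect(names(raw), par_keys)])
  params <- do.call(model_params, pars)
  list(params = params,
       D = if ("D" %in% names(raw)) raw$D else NULL,
       seed = if ("seed" %in% names(raw)) raw$seed else NULL,
       settings = raw[intersect(names(raw), setdiff(run_keys,
                                                    c("D", "seed")))])
}

#' Write a run configuration
#'
#' @param params a [model_params] object.
#' @param path output path (`.yaml` or `.json`).
#' @param D,seed optional noise intensity and RNG seed to record.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path, D = NULL, seed = NULL) {
  x <- unclass(params)
  if (!is.null(D)) x$D <- D
  if (!is.null(seed)) x$seed <- seed
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(x, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Landscape as a long-format table
#'
#' @param land a `landscape` object.
#' @return data frame with columns `x1`, `x2`, `P`, `U` (one row per cell).
#' @export
landscape_table <- function(land) {
  data.frame(x1 = rep(land$x1, times = length(land$x2)),
             x2 = rep(land$x2, each = length(land$x1)),
             P = as.vector(land$P), U = as.vector(land$U))
}

#' Reproduce the package's benchmark analyses as data tables
#'
#' Runs the canonical analyses of the circuit at its reference parameter
#' sets and writes tab-separated tables plus a JSON summary to `outdir`:
#' \describe{
#'   \item{`"fixed_points"`}{the five fixed points (three stable, two
#'     saddles) at `a1 = 0.8`, `a2 = 0.85` -> `fixed_points.tsv`.}
#'   \item{`"phase_diagram"`}{region codes over the `(a1, a2)` plane ->
#'     `phase_diagram.tsv` (long) and `phase_labels.tsv` (dense matrix).}
#'   \item{`"mfpt"`}{steepest-descent and exact `tau_BS(D)`, `tau_SB(D)`
#'     curves with the crossing `D_c` -> `mfpt.tsv`.}
#'   \item{`"occupancy"`}{basin occupancies versus noise intensity at
#'     `a1 = 0.8`, `a2 = 0.85` -> `occupancy.tsv`.}
#'   \item{`"bifurcation"`}{fixed-point branches versus `a1` at `a2 = 0.8`
#'     -> `bifurcation.tsv`.}
#' }
#'
#' @param tag one of `"fixed_points"`, `"phase_diagram"`, `"mfpt"`,
#'   `"occupancy"`, `"bifurcation"`.
#' @param outdir output directory (created if needed).
#' @param seed RNG seed for the stochastic tables.
#' @param fast logical; `TRUE` shrinks grids and run lengths (used by the
#'   examples and tests).
#' @return named list of the tables, invisibly; files are written as a side
#'   effect.
#' @export
reproduce_figure <- function(tag = c("fixed_points", "phase_diagram",
                                     "mfpt", "occupancy", "bifurcation"),
                             outdir = ".", seed = 1, fast = FALSE) {
  tag <- match.arg(tag)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- model_params(a1 = 0.8, a2 = 0.85)
  out <- switch(tag,
    fixed_points = {
      fps <- find_fixed_points(p)
      write_tsv(fps, file.path(outdir, "fixed_points.tsv"))
      list(fixed_points = fps)
    },
    phase_diagram = {
      ng <- if (fast) 31 else 151
      g <- seq(0.02, 1.5, length.out = ng)
      pm <- phase_diagram(p, list(name = "a1", values = g),
                          list(name = "a2", values = g),
                          seeds_per_axis = if (fast) 200 else 400)
      long <- data.frame(a1 = rep(g, times = ng), a2 = rep(g, each = ng),
                         label = as.vector(pm$cell_label),
                         n_stable = as.vector(pm$n_stable))
      write_tsv(long, file.path(outdir, "phase_diagram.tsv"))
      write_tsv(as.data.frame(pm$cell_label),
                file.path(outdir, "phase_labels.tsv"))
      list(phase_map = pm)
    },
    mfpt = {
      pot <- reduced_potential(p, stationary_x1(p, "high"))
      Ds <- seq(0.05, 0.12, length.out = if (fast) 8 else 29)
      tab <- data.frame(
        D = Ds,
        tau_BS_kramers = vapply(Ds, function(D)
          mfpt_kramers(pot, D, "BS")$value, numeric(1)),
        tau_SB_kramers = vapply(Ds, function(D)
          mfpt_kramers(pot, D, "SB")$value, numeric(1)),
        tau_BS_integral = vapply(Ds, function(D)
          mfpt_integral(pot, D, direction = "BS")$value, numeric(1)),
        tau_SB_integral = vapply(Ds, function(D)
          mfpt_integral(pot, D, direction = "SB")$value, numeric(1)))
      Dc <- find_noise_threshold(pot)
      write_tsv(tab, file.path(outdir, "mfpt.tsv"))
      jsonlite::write_json(list(D_c = as.numeric(Dc),
                                barriers = as.list(barrier_heights(pot))),
                           file.path(outdir, "mfpt_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      list(mfpt = tab, D_c = Dc)
    },
    occupancy = {
      fps <- find_fixed_points(p)
      Ds <- c(0.01, 0.04, 0.07, 0.1)
      set.seed(seed)
      rows <- lapply(Ds, function(D) {
        occ <- estimate_occupancy(p, D, fps,
                                  t_end = if (fast) 300 else 2000,
                                  burn_in = if (fast) 30 else 200,
                                  n_replicates = if (fast) 4 else 8)
        data.frame(D = D, phenotype = names(occ$probability),
                   probability = occ$probability, se = occ$se)
      })
      tab <- do.call(rbind, rows)
      write_tsv(tab, file.path(outdir, "occupancy.tsv"))
      list(occupancy = tab)
    },
    bifurcation = {
      pb <- model_params(a1 = 0.8, a2 = 0.8)
      g <- seq(0.3, 0.95, length.out = if (fast) 33 else 131)
      bif <- bifurcation_scan(pb, "a1", g,
                              seeds_per_axis = if (fast) 200 else 400)
      write_tsv(bif, file.path(outdir, "bifurcation.tsv"))
      list(bifurcation = bif)
    })
  invisible(out)
}
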