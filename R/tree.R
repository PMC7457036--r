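#' Morphometry specification for synthetic coronary tree generation
#'
#' Describes the order-structured statistics used to generate a coronary
#' arterial tree: junction counts and, per diameter-defined order 0..6, the
#' admissible diameter range and mean, mean segment length, and the passive
#' pressure-diameter constants of the sigmoidal diameter law.  The default
#' table is a synthetic morphometry chosen so that the default 400-vessel
#' tree has an aggregate resistance compatible with the calibrated flows;
#' each "vessel" is a lumped-equivalent segment, not an anatomical arteriole.
#'
#' Vessel counts obey the structural identity
#' \code{n_vessels = 1 + 2 * n_bif + 3 * n_trif}.
#'
#' @param n_bif number of bifurcations.
#' @param n_trif number of trifurcations.
#' @param orders data frame with columns \code{order}, \code{diam_min},
#'   \code{diam_mean}, \code{diam_max} (cm), \code{len_mean} (cm),
#'   \code{phi_p} (mmHg), \code{Cp} (mmHg); one row per order 0..6.
#' @param ap_frac,bp_frac asymptotic maximal/minimal radius of a vessel as a
#'   fraction of its reference diameter (\code{Ap = ap_frac * D},
#'   \code{Bp = bp_frac * D}); must satisfy \code{ap_frac > bp_frac > 0} and
#'   \code{ap_frac + bp_frac = 1} so the reference diameter is attained at
#'   transvascular pressure \code{phi_p}.
#' @param len_cv coefficient of variation of segment lengths.
#' @param seed integer random seed; generation is deterministic per seed.
#' @return An object of class \code{morphometry_spec}.
#' @examples
#' spec <- morphometry_spec(n_bif = 1, n_trif = 0, seed = 1)
#' tr <- generate_tree(spec)
#' nrow(tr)  # 3 vessels
#' @export
morphometry_spec <- function(n_bif = 195, n_trif = 3,
                             orders = default_order_table(),
                             ap_frac = 0.65, bp_frac = 0.35,
                             len_cv = 0.15, seed = 20L) {
  if (n_bif < 0 || n_trif < 0 || (n_bif + n_trif) < 1)
    stop("at least one junction is required", call. = FALSE)
  req <- c("order", "diam_min", "diam_mean", "diam_max", "len_mean",
           "phi_p", "Cp")
  if (!all(req %in% names(orders)))
    stop("'orders' must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  with(orders, {
    if (any(diam_min > diam_mean | diam_mean > diam_max | diam_min <= 0))
      stop("per-order diameter ranges are degenerate", call. = FALSE)
    if (any(len_mean <= 0) || any(Cp <= 0))
      stop("lengths and Cp must be positive", call. = FALSE)
  })
  if (!(ap_frac > bp_frac && bp_frac > 0))
    stop("'ap_frac' must exceed 'bp_frac' > 0", call. = FALSE)
  structure(list(n_bif = as.integer(n_bif), n_trif = as.integer(n_trif),
                 n_vessels = 1L + 2L * as.integer(n_bif) + 3L * as.integer(n_trif),
                 orders = orders[order(orders$order), , drop = FALSE],
                 ap_frac = ap_frac, bp_frac = bp_frac,
                 len_cv = len_cv, seed = as.integer(seed)),
            class = "morphometry_spec")
}

#' Default per-order morphometry table
#'
#' Synthetic lumped-equivalent morphometry for diameter-defined orders 0-6.
#' Diameters and lengths are in cm; \code{phi_p} (transvascular pressure at
#' the mean radius) and \code{Cp} (passive bandwidth) are in mmHg.
#'
#' @return A data frame with one row per order.
#' @export
default_order_table <- function() {
  data.frame(
    order     = 0:6,
    diam_min  = c(0.044, 0.062, 0.090, 0.125, 0.176, 0.250, 0.368),
    diam_mean = c(0.052, 0.072, 0.105, 0.145, 0.204, 0.289, 0.420),
    diam_max  = c(0.060, 0.082, 0.120, 0.165, 0.232, 0.328, 0.472),
    len_mean  = c(0.18, 0.28, 0.40, 0.55, 0.70, 0.90, 1.20),
    phi_p     = c(35, 40, 45, 50, 55, 60, 65),
    Cp        = c(22, 22, 24, 26, 28, 30, 32)
  )
}

# run expr with a private RNG stream seeded by `seed`
with_tree_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic order-structured coronary tree
#'
#' Grows a rooted tree with exactly the requested numbers of bifurcations
#' and trifurcations by repeatedly expanding a randomly chosen open leaf,
#' assigns diameter-defined orders by rescaling the Strahler order so the
#' root has order 6 and leaves order 0, and then samples per-vessel
#' morphometry with \code{\link{assign_vessel_properties}}.  Generation is
#' deterministic for a fixed \code{spec$seed}.
#'
#' @param spec a \code{\link{morphometry_spec}}.
#' @return A \code{coronary_tree}: a data frame with columns \code{id},
#'   \code{parent_id} (NA for the root), \code{order}, \code{diameter},
#'   \code{length}, \code{Ap}, \code{Bp}, \code{phi_p}, \code{Cp}.
#' @export
generate_tree <- function(spec) {
  stopifnot(inherits(spec, "morphometry_spec"))
  n_junc <- spec$n_bif + spec$n_trif
  with_tree_seed(spec$seed, {
    arity <- rep(2L, n_junc)
    if (spec$n_trif > 0)
      arity[sample.int(n_junc, spec$n_trif)] <- 3L
    parent <- rep(NA_integer_, spec$n_vessels)
    n <- 1L                      # vessels created so far (vessel 1 = root)
    open <- 1L                   # expandable leaves
    for (j in seq_len(n_junc)) {
      pick <- if (length(open) == 1L) 1L else sample.int(length(open), 1L)
      v <- open[pick]
      open <- open[-pick]
      kids <- n + seq_len(arity[j])
      parent[kids] <- v
      n <- n + arity[j]
      open <- c(open, kids)
    }
    tr <- data.frame(id = seq_len(spec$n_vessels), parent_id = parent)
    tr$order <- rescale_orders(strahler_order(tr),
                               max(spec$orders$order), min(spec$orders$order))
    tr <- assign_vessel_properties(as_coronary_tree(tr), spec)
    validate_tree(tr)
    tr
  })
}

# Strahler order computed leaves-up: leaves are 1; a parent whose maximal
# child order occurs more than once is promoted by one.
strahler_order <- function(tr) {
  n <- nrow(tr)
  kids <- split(seq_len(n), factor(tr$parent_id, levels = tr$id))
  s <- integer(n)
  # process in reverse creation order: children always have larger ids
  for (v in rev(seq_len(n))) {
    ch <- kids[[v]]
    if (length(ch) == 0L) {
      s[v] <- 1L
    } else {
      m <- max(s[ch])
      s[v] <- if (sum(s[ch] == m) > 1L) m + 1L else m
    }
  }
  s
}

# map Strahler orders [1, s_root] monotonically onto [o_min, o_max]
rescale_orders <- function(s, o_max, o_min = 0L) {
  s_root <- max(s)
  if (s_root == 1L) return(rep(o_max, length(s)))
  as.integer(round((s - 1L) * (o_max - o_min) / (s_root - 1L)) + o_min)
}

#' Assign per-vessel morphometric and passive-pressure properties
#'
#' Samples each vessel's reference diameter uniformly within its order's
#' configured range (collapsed ranges give exactly the order mean) and its
#' length from a truncated normal around the order's mean length; derives
#' the sigmoidal diameter-law constants \code{Ap = ap_frac * D},
#' \code{Bp = bp_frac * D} and copies the order's \code{phi_p}, \code{Cp}.
#'
#' @param tree a \code{coronary_tree} with at least \code{id},
#'   \code{parent_id}, \code{order}.
#' @param spec a \code{\link{morphometry_spec}}.
#' @return The tree with all vessel property columns filled.
#' @export
assign_vessel_properties <- function(tree, spec) {
  stopifnot(inherits(spec, "morphometry_spec"))
  ot <- spec$orders
  idx <- match(tree$order, ot$order)
  if (anyNA(idx))
    stop("tree contains orders absent from the morphometry table",
         call. = FALSE)
  n <- nrow(tree)
  u <- stats::runif(n)
  # symmetric triangular-ish draw around the mean inside [min, max]
  lo <- ot$diam_min[idx]; hi <- ot$diam_max[idx]; mu <- ot$diam_mean[idx]
  tree$diameter <- ifelse(u < 0.5, lo + (mu - lo) * 2 * u,
                          mu + (hi - mu) * (2 * u - 1))
  len <- stats::rnorm(n, ot$len_mean[idx], spec$len_cv * ot$len_mean[idx])
  tree$length <- pmax(len, 0.3 * ot$len_mean[idx])
  tree$Ap <- spec$ap_frac * tree$diameter
  tree$Bp <- spec$bp_frac * tree$diameter
  tree$phi_p <- ot$phi_p[idx]
  tree$Cp <- ot$Cp[idx]
  as_coronary_tree(tree)
}

as_coronary_tree <- function(df) {
  class(df) <- unique(c("coronary_tree", class(df)))
  df
}

#' Validate a coronary tree
#'
#' Checks the structural invariants: unique ids, a single root, no orphans
#' or cycles (connectivity), junction arity 2 or 3, non-increasing order
#' from root to leaf, and positive geometry with \code{Ap > Bp > 0} where
#' the property columns are present.
#'
#' @param tree a \code{coronary_tree} data frame.
#' @return Invisibly, a list with \code{n_vessels}, \code{n_bif},
#'   \code{n_trif}, \code{n_leaves}.
#' @export
validate_tree <- function(tree) {
  if (anyDuplicated(tree$id))
    stop("duplicate vessel ids: ",
         paste(unique(tree$id[duplicated(tree$id)]), collapse = ", "),
         call. = FALSE)
  root <- which(is.na(tree$parent_id))
  if (length(root) != 1L)
    stop("tree must have exactly one root (found ", length(root), ")",
         call. = FALSE)
  pidx <- match(tree$parent_id, tree$id)
  orphan <- which(!is.na(tree$parent_id) & is.na(pidx))
  if (length(orphan))
    stop("orphan vessels reference missing parents: ",
         paste(tree$id[orphan], collapse = ", "), call. = FALSE)
  # connectivity/acyclicity: walk each vessel to the root
  n <- nrow(tree)
  for (v in seq_len(n)) {
    seen <- 0L; cur <- v
    while (!is.na(pidx[cur])) {
      cur <- pidx[cur]
      seen <- seen + 1L
      if (seen > n)
        stop("cycle detected involving vessel id ", tree$id[v], call. = FALSE)
    }
    if (cur != root)
      stop("vessel id ", tree$id[v], " is disconnected from the root",
           call. = FALSE)
  }
  nkid <- tabulate(pidx[!is.na(pidx)], nbins = n)
  if (any(!nkid %in% c(0L, 2L, 3L)))
    stop("junction arity must be 2 or 3; offending vessel ids: ",
         paste(tree$id[!nkid %in% c(0L, 2L, 3L)], collapse = ", "),
         call. = FALSE)
  if (!is.null(tree$order)) {
    bad <- !is.na(pidx) & tree$order > tree$order[pidx]
    if (any(bad))
      stop("vessel order exceeds parent order for ids: ",
           paste(tree$id[bad], collapse = ", "), call. = FALSE)
  }
  if (!is.null(tree$Ap)) {
    if (any(tree$Ap <= tree$Bp | tree$Bp <= 0))
      stop("vessel radii must satisfy Ap > Bp > 0", call. = FALSE)
    if (any(tree$length <= 0))
      stop("vessel lengths must be positive", call. = FALSE)
  }
  invisible(list(n_vessels = n,
                 n_bif = sum(nkid == 2L),
                 n_trif = sum(nkid == 3L),
                 n_leaves = sum(nkid == 0L)))
}

#' Write / read a coronary tree file
#'
#' Flat tab-delimited text, one vessel per row, columns \code{id},
#' \code{parent_id} (empty for the root), \code{order}, \code{diameter},
#' \code{length}, \code{Ap}, \code{Bp}, \code{phi_p}, \code{Cp}.  A
#' write-then-read round trip reproduces the tree exactly at the written
#' precision (17 significant digits, i.e. lossless for doubles).
#'
#' @param tree a validated \code{coronary_tree}.
#' @param path file path.
#' @return \code{read_tree} returns a validated \code{coronary_tree};
#'   \code{write_tree} returns \code{path} invisibly.
#' @export
write_tree <- function(tree, path) {
  validate_tree(tree)
  cols <- c("id", "parent_id", "order", "diameter", "length",
            "Ap", "Bp", "phi_p", "Cp")
  df <- as.data.frame(tree)[, cols]
  for (j in c("diameter", "length", "Ap", "Bp", "phi_p", "Cp"))
    df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      na.strings = "", stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse tree file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  req <- c("id", "parent_id", "order", "diameter", "length",
           "Ap", "Bp", "phi_p", "Cp")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("tree file '", path, "' lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (j in setdiff(req, c("id", "parent_id", "order"))) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))) &
                     !is.na(df[[j]]))[1]
      stop("non-numeric value in column '", j, "' at line ", bad + 1L,
           " of '", path, "'", call. = FALSE)
    }
  }
  tr <- as_coronary_tree(df)
  validate_tree(tr)
  tr
}

#' Summarize tree structure
#'
#' @param tree a \code{coronary_tree}.
#' @return A list with vessel, bifurcation, trifurcation and leaf counts and
#'   the per-order vessel counts.
#' @export
tree_summary <- function(tree) {
  v <- validate_tree(tree)
  v$per_order <- table(tree$order)
  v
}
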