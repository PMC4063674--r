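#' Specify a brute-force parameter grid
#'
#' The screen varies seven maximal conductances (\eqn{\bar g_{SynS}},
#' \eqn{\bar g_{SynG}}, \eqn{\bar g_P}, \eqn{\bar g_{K2}}, \eqn{\bar g_h},
#' \eqn{\bar g_{CaS}}, \eqn{\bar g_{Leak}}) over percent-of-canonical levels
#' (default 0, 25, 50, 75, 100, 125, 150, 175) and the leak reversal
#' potential over -70, -65, -60, -55, -50 mV: 8^7 x 5 = 10,485,760 grid
#' points, of which 8^5 x 5 = 163,840 are isolated (both synaptic
#' conductances zero).
#'
#' @param levels_pct percent levels applied to each swept conductance
#' @param e_leak_mv leak reversal potential levels (mV)
#' @param fix named list pinning parameters to a single level, e.g.
#'   `list(SynS = 0, SynG = 0)` for the isolated subgrid or
#'   `list(CaS = 100, h = 100, SynS = 100, SynG = 100)` for the
#'   canonical-restricted coupled subgrid (names: the seven conductances
#'   and `E_Leak`)
#' @param restrict optional predicate `function(df)` returning a logical
#'   vector over enumerated rows (applied on top of `fix`)
#' @return An object of class `hco_grid`.
#' @export
grid_spec <- function(levels_pct = c(0, 25, 50, 75, 100, 125, 150, 175),
                      e_leak_mv = c(-70, -65, -60, -55, -50),
                      fix = list(), restrict = NULL) {
  stopifnot(length(levels_pct) > 0, length(e_leak_mv) > 0)
  cols <- c(.swept_conductances, "E_Leak")
  levels <- c(stats::setNames(rep(list(levels_pct), 7), .swept_conductances),
              list(E_Leak = e_leak_mv))
  if (length(fix)) {
    bad <- setdiff(names(fix), cols)
    if (length(bad)) stop("unknown parameters in fix: ", paste(bad, collapse = ", "))
    for (nm in names(fix)) levels[[nm]] <- sort(as.numeric(fix[[nm]]))
  }
  structure(list(levels = levels, restrict = restrict), class = "hco_grid")
}

#' Number of grid points
#'
#' Closed form (product of per-parameter level counts) when no predicate
#' restriction is present; otherwise the predicate is applied to the
#' enumeration.
#'
#' @param g an [grid_spec()] object
#' @return Integer-valued count.
#' @export
grid_size <- function(g) {
  stopifnot(inherits(g, "hco_grid"))
  n <- prod(vapply(g$levels, length, numeric(1)))
  if (is.null(g$restrict)) return(n)
  if (n > 5e6) stop("predicate-restricted counting needs full enumeration; grid too large")
  nrow(enumerate_grid(g))
}

#' Enumerate grid points as parameter-level rows
#'
#' Deterministic lexicographic order: the first column
#' (\eqn{\bar g_{SynS}}) varies slowest, `E_Leak` fastest. The enumeration
#' is index-addressable, so arbitrary windows of a huge grid can be
#' produced without materializing the whole of it.
#'
#' @param g an [grid_spec()] object
#' @param from 1-based index of the first vector to return
#' @param n number of vectors (default: through the end of the grid)
#' @return data.frame with the seven conductance percent levels and
#'   `E_Leak` (mV), plus a `grid_index` column.
#' @export
enumerate_grid <- function(g, from = 1, n = Inf) {
  stopifnot(inherits(g, "hco_grid"))
  sizes <- vapply(g$levels, length, numeric(1))
  total <- prod(sizes)
  if (from > total) {
    empty <- c(lapply(g$levels, function(x) numeric(0)), list(grid_index = numeric(0)))
    return(as.data.frame(empty))
  }
  idx <- seq(from, min(total, from + n - 1))
  ncols <- length(sizes)
  radix <- rev(cumprod(rev(c(sizes[-1], 1)))) # place value of each column
  out <- vector("list", ncols)
  rem <- idx - 1
  for (j in seq_len(ncols)) {
    d <- rem %/% radix[j]
    rem <- rem - d * radix[j]
    out[[j]] <- g$levels[[j]][d + 1]
  }
  names(out) <- names(g$levels)
  df <- as.data.frame(out)
  df$grid_index <- idx
  if (!is.null(g$restrict)) {
    keep <- g$restrict(df)
    if (!any(keep)) warning("restriction matches no grid points")
    df <- df[keep, , drop = FALSE]
  }
  df
}

# ---- instance store ----------------------------------------------------

#' Open (or create) a sweep store
#'
#' A store is a directory holding one `instances.csv` table (one row per
#' simulated grid point, keyed by the parameter tuple / `grid_index`) and a
#' `meta.json` provenance sidecar (solver settings, package version).
#' Mixing results produced under different solver settings is refused.
#'
#' @param path store directory
#' @return An object of class `hco_store`.
#' @export
hco_store <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  structure(list(path = path,
                 csv = file.path(path, "instances.csv"),
                 meta = file.path(path, "meta.json")),
            class = "hco_store")
}

.store_meta <- function(proto, backend) {
  list(dt = proto$dt, settle = proto$settle, record = proto$record,
       warmup = proto$warmup, threshold = proto$threshold,
       backend = backend,
       version = as.character(utils::packageVersion("hcosweep")))
}

.meta_write <- function(store, meta) {
  writeLines(.json_obj(meta), store$meta)
}

.meta_read <- function(store) {
  if (!file.exists(store$meta)) return(NULL)
  txt <- paste(readLines(store$meta), collapse = "")
  # minimal flat-JSON parse (numbers and strings)
  txt <- gsub("[{}\"]", "", txt)
  kv <- strsplit(strsplit(txt, ",")[[1]], ":")
  vals <- lapply(kv, function(x) {
    v <- trimws(x[2])
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) v else num
  })
  stats::setNames(vals, vapply(kv, function(x) trimws(x[1]), character(1)))
}

.json_obj <- function(x) {
  enc <- vapply(x, function(v)
    if (is.character(v)) paste0('"', v, '"') else format(v, digits = 15),
    character(1))
  paste0("{", paste(sprintf('"%s": %s', names(x), enc), collapse = ", "), "}")
}

#' Read the full instance table of a store
#'
#' @param store an [hco_store()] object
#' @return data.frame of instance records (zero rows if empty).
#' @export
read_store <- function(store) {
  stopifnot(inherits(store, "hco_store"))
  if (!file.exists(store$csv)) return(.empty_instances())
  utils::read.csv(store$csv, stringsAsFactors = FALSE)
}

.empty_instances <- function() {
  data.frame(grid_index = integer(0), SynS = numeric(0), SynG = numeric(0),
             P = numeric(0), K2 = numeric(0), h = numeric(0),
             CaS = numeric(0), Leak = numeric(0), E_Leak = numeric(0),
             category = character(0), realistic = logical(0),
             period = numeric(0), period_cv = numeric(0), freq = numeric(0),
             duty = numeric(0), phase = numeric(0),
             min_V_A = numeric(0), min_V_B = numeric(0),
             n_spikes_A = integer(0), n_spikes_B = integer(0),
             failed = logical(0))
}

# simulate + classify one grid row into an instance record
.instance_record <- function(row, ics, proto, backend) {
  lv <- unlist(row[.swept_conductances])
  p <- param_vector(lv, E_Leak_mV = row$E_Leak)
  tr <- simulate_instance(p, ics, proto, backend = backend)
  cl <- classify_trace(tr)
  data.frame(grid_index = row$grid_index,
             SynS = row$SynS, SynG = row$SynG, P = row$P, K2 = row$K2,
             h = row$h, CaS = row$CaS, Leak = row$Leak, E_Leak = row$E_Leak,
             category = cl$category, realistic = isTRUE(cl$realistic),
             period = cl$period, period_cv = cl$period_cv, freq = cl$freq,
             duty = cl$duty, phase = cl$phase,
             min_V_A = tr$min_V[["A"]], min_V_B = tr$min_V[["B"]],
             n_spikes_A = nrow(tr$spikes$A), n_spikes_B = nrow(tr$spikes$B),
             failed = tr$failed)
}

#' Run (or resume) a sweep over a grid
#'
#' Simulates and classifies every grid point exactly once, appending
#' records to the store in chunks so an interrupted sweep resumes where it
#' stopped; rerunning a completed sweep performs zero new simulations.
#' All instances share the canonical initial conditions.
#'
#' @param g an [grid_spec()] object
#' @param store an [hco_store()] object (or a path)
#' @param proto an [sim_protocol()] object
#' @param backend integration backend (see [integrate_hco()])
#' @param chunk_size records per append (default 128)
#' @param verbose print progress
#' @return A sweep report (class `hco_sweep_report`): counts per category,
#'   realistic counts, failures, new/total instance numbers.
#' @export
run_sweep <- function(g, store, proto = sim_protocol(), backend = "euler",
                      chunk_size = 128, verbose = FALSE) {
  if (is.character(store)) store <- hco_store(store)
  meta <- .store_meta(proto, backend)
  old <- .meta_read(store)
  if (!is.null(old)) {
    for (nm in names(meta))
      if (!identical(as.character(old[[nm]]), as.character(meta[[nm]])))
        stop("store was produced under different settings (", nm,
             "); refusing to mix")
  } else {
    .meta_write(store, meta)
  }
  grid <- enumerate_grid(g)
  done <- read_store(store)
  todo <- grid[!(grid$grid_index %in% done$grid_index), , drop = FALSE]
  n_new <- nrow(todo)
  if (n_new) {
    ics <- canonical_initial_conditions(proto)
    starts <- seq(1, n_new, by = chunk_size)
    for (s0 in starts) {
      rows <- todo[s0:min(n_new, s0 + chunk_size - 1), , drop = FALSE]
      recs <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i)
        .instance_record(rows[i, ], ics, proto, backend)))
      utils::write.table(recs, store$csv, sep = ",", row.names = FALSE,
                         col.names = !file.exists(store$csv), append = file.exists(store$csv))
      if (verbose)
        message(sprintf("sweep: %d / %d instances",
                        min(n_new, s0 + chunk_size - 1), n_new))
    }
  }
  all <- read_store(store)
  all <- all[all$grid_index %in% grid$grid_index, , drop = FALSE]
  tab <- table(all$category)
  structure(list(n_total = nrow(all), n_new = n_new,
                 categories = tab,
                 n_hco = sum(all$category == "HCO"),
                 n_realistic_hco = sum(all$category == "HCO" & all$realistic),
                 n_burster = sum(all$category == "burster"),
                 n_realistic_burster = sum(all$category == "burster" & all$realistic),
                 n_failed = sum(all$failed)),
            class = "hco_sweep_report")
}

#' @export
print.hco_sweep_report <- function(x, ...) {
  cat("<hco_sweep_report>\n")
  cat(sprintf("  instances: %d (%d new this run; %d failed)\n",
              x$n_total, x$n_new, x$n_failed))
  cat("  categories:\n")
  for (nm in names(x$categories))
    cat(sprintf("    %-16s %d\n", nm, x$categories[[nm]]))
  cat(sprintf("  HCOs %d (realistic %d); bursters %d (realistic %d)\n",
              x$n_hco, x$n_realistic_hco, x$n_burster, x$n_realistic_burster))
  invisible(x)
}

# the four named database-style views
.views <- list(
  hco = function(d) d$category == "HCO",
  realistic_hco = function(d) d$category == "HCO" & d$realistic,
  burster = function(d) d$category == "burster",
  realistic_burster = function(d) d$category == "burster" & d$realistic
)

#' Query a group of instances from a store
#'
#' Named views mirror the database views of the original screen:
#' `"hco"`, `"realistic_hco"`, `"burster"`, `"realistic_burster"`; a
#' predicate function over the instance table can be given instead.
#'
#' @param store an [hco_store()] object
#' @param view view name or `function(df)` returning a logical vector
#' @return data.frame of the selected instance records.
#' @export
query_group <- function(store, view) {
  d <- read_store(store)
  pred <- if (is.function(view)) view
  else {
    if (!view %in% names(.views)) stop("unknown view: ", view)
    .views[[view]]
  }
  d[which(pred(d)), , drop = FALSE]
}

#' Cross-reference isolated instances with the coupled instances they compose
#'
#' For every isolated instance (both synaptic conductances zero) in the
#' store, counts the coupled records (any nonzero synaptic combination)
#' that share its intrinsic parameter tuple
#' (\eqn{\bar g_P, \bar g_{K2}, \bar g_h, \bar g_{CaS}, \bar g_{Leak},
#' E_{Leak}}) and are classified HCO / realistic HCO.
#'
#' @param store an [hco_store()] object
#' @return data.frame: one row per isolated instance with its category,
#'   `n_coupled` (coupled records sharing the tuple), `n_hco`,
#'   `n_realistic_hco`. A warning is raised when coupled coverage is
#'   missing for some isolated instances.
#' @export
cross_reference_hco_components <- function(store) {
  d <- read_store(store)
  iso <- d[d$SynS == 0 & d$SynG == 0, , drop = FALSE]
  cpl <- d[d$SynS != 0 | d$SynG != 0, , drop = FALSE]
  if (!nrow(iso)) stop("store holds no isolated instances")
  key <- function(x) paste(x$P, x$K2, x$h, x$CaS, x$Leak, x$E_Leak, sep = "|")
  iso_key <- key(iso)
  cpl_key <- key(cpl)
  out <- data.frame(iso[, c("grid_index", "P", "K2", "h", "CaS", "Leak",
                            "E_Leak", "category", "realistic")],
                    n_coupled = as.integer(table(factor(cpl_key, levels = iso_key))[iso_key]),
                    n_hco = as.integer(table(factor(cpl_key[cpl$category == "HCO"],
                                                    levels = iso_key))[iso_key]),
                    n_realistic_hco = as.integer(
                      table(factor(cpl_key[cpl$category == "HCO" & cpl$realistic],
                                   levels = iso_key))[iso_key]))
  if (any(out$n_coupled == 0))
    warning(sum(out$n_coupled == 0),
            " isolated instances have no coupled coverage in this store")
  out
}
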