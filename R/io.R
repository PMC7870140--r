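# Clone-table file formats.  Canonical dialect: tab-separated text with a
# header row; immunoSEQ-style column names are mapped through an alias table
# so cohort exports and generic tables flow through the same reader.

clone_table_aliases <- list(
  clone_id = c("clone_id", "rearrangement", "nucleotide", "cdr3_nt",
               "cdr3_rearrangement", "sequence"),
  count = c("count", "reads", "templates", "umi_count", "clone_count",
            "seq_reads"),
  vd_insertions = c("vd_insertions", "n1_insertions", "n1insertion"),
  dj_insertions = c("dj_insertions", "n2_insertions", "n2insertion"),
  productive = c("productive", "frame_type"),
  age = c("age", "age_years"),
  t_recruit = c("t_recruit", "recruitment_time")
)

resolve_column <- function(nms, field, dialect) {
  if (!is.null(dialect[[field]])) {
    if (dialect[[field]] %in% nms) return(dialect[[field]])
    return(NULL)
  }
  hit <- intersect(clone_table_aliases[[field]], tolower(nms))
  if (length(hit) == 0) return(NULL)
  nms[match(hit[1], tolower(nms))]
}

#' Read a clone table
#'
#' Reads a delimited clone table (one row per clone) and standardizes its
#' columns. The read-count column is mandatory and must hold positive
#' integers. When both junction insertion-count columns are present
#' (VD and DJ), a logical `zero_insertions` column is derived as
#' `vd + dj == 0`: a clone is dated as early only when it has zero inserted
#' nucleotides at *both* junctions.
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect Optional named list overriding column resolution, e.g.
#'   `list(count = "myCount", delim = ",")`. Fields: `clone_id`, `count`,
#'   `vd_insertions`, `dj_insertions`, `age`, `t_recruit`, `delim`.
#' @return A tibble with standardized columns (`clone_id`, `count`, and
#'   `zero_insertions`, `t_recruit`, `age` when available), other columns
#'   retained as-is.
#' @export
read_clone_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- dialect$delim %||% "\t"
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (nrow(tab) == 0) stop("empty clone table: ", path, call. = FALSE)
  cnt_col <- resolve_column(names(tab), "count", dialect)
  if (is.null(cnt_col))
    stop("no read-count column found (looked for: ",
         paste(clone_table_aliases$count, collapse = ", "), ")",
         call. = FALSE)
  cnt <- tab[[cnt_col]]
  if (!is.numeric(cnt) || any(!is.finite(cnt)) || any(cnt != round(cnt)) ||
      any(cnt < 1))
    stop("count column '", cnt_col, "' must hold positive integers",
         call. = FALSE)
  out <- tab
  names(out)[match(cnt_col, names(out))] <- "count"
  for (f in c("clone_id", "t_recruit", "age")) {
    col <- resolve_column(names(tab), f, dialect)
    if (!is.null(col) && col != f) names(out)[match(col, names(out))] <- f
  }
  vd <- resolve_column(names(tab), "vd_insertions", dialect)
  dj <- resolve_column(names(tab), "dj_insertions", dialect)
  if (!is.null(vd) && !is.null(dj)) {
    out$zero_insertions <- tab[[vd]] + tab[[dj]] == 0
  }
  if (!"clone_id" %in% names(out)) out$clone_id <- seq_len(nrow(out))
  out
}

#' Write a clone table
#'
#' Writes a tibble as a tab-separated clone table with a header row, the
#' canonical dialect of [read_clone_table()]. A snapshot or cohort-individual
#' tibble round-trips through write and read unchanged (a `size` column is
#' written as `count` when no `count` column exists, so simulator snapshots
#' export directly).
#'
#' @param data A data frame with a `count` (or `size`) column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clone_table <- function(data, path) {
  if (!"count" %in% names(data)) {
    if ("size" %in% names(data)) {
      data <- dplyr::rename(data, count = "size")
    } else {
      stop("data must have a 'count' (or 'size') column", call. = FALSE)
    }
  }
  readr::write_tsv(data, path, progress = FALSE)
  invisible(path)
}

#' Write a cohort as per-individual clone tables with a manifest
#'
#' Exports each individual of a cohort tibble to
#' `<dir>/individual_<id>.tsv` and writes a tab-separated manifest
#' (`individual_id`, `age`, `file`) to `<dir>/manifest.tsv`.
#'
#' @param cohort A cohort tibble from [sample_cohort()].
#' @param dir Output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(all(c("individual_id", "age", "count") %in% names(cohort)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- cohort |>
    dplyr::distinct(.data$individual_id, .data$age) |>
    dplyr::mutate(file = sprintf("individual_%s.tsv", .data$individual_id))
  purrr::walk2(manifest$individual_id, manifest$file, function(id, f) {
    write_clone_table(dplyr::filter(cohort, .data$individual_id == id),
                      file.path(dir, f))
  })
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"), progress = FALSE)
  invisible(manifest)
}

#' Export a snapshot with a run-metadata sidecar
#'
#' Writes a simulator snapshot as a tab-separated clone table
#' (via [write_clone_table()]) together with a YAML sidecar
#' (`<path>.yml`) recording the simulation configuration and seed, so a run
#' can be reproduced from its outputs alone.
#'
#' @param snapshot A snapshot tibble from [simulate_exact()] or
#'   [simulate_meanfield()].
#' @param path Output path for the clone table.
#' @param config The [sim_config()] that produced the snapshot (optional).
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(snapshot, path, config = NULL) {
  write_clone_table(snapshot, path)
  if (!is.null(config)) {
    meta <- list(
      params = unclass(config$params),
      t_end = config$t_end,
      record_times = config$record_times,
      seed = config$seed,
      mode = config$mode
    )
    yaml::write_yaml(meta, paste0(path, ".yml"))
  }
  invisible(path)
}

#' Read a memory-fraction table
#'
#' Reads a two-column delimited table (age in years, fraction of T cells with
#' memory phenotype) and returns a piecewise-linear interpolation function
#' with constant extrapolation beyond the tabulated range, for use as the
#' `memory_fraction_fn` of [normalize_clone_sizes()].
#'
#' @param path Path to a delimited text file whose first two columns are age
#'   and fraction.
#' @return A function `age -> fraction`.
#' @export
read_memory_fraction_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_delim(path, delim = "\t", show_col_types = FALSE,
                           progress = FALSE)
  if (ncol(tab) < 2 || nrow(tab) == 0)
    stop("expected a two-column (age, fraction) table", call. = FALSE)
  age <- tab[[1]]
  frac <- tab[[2]]
  if (is.unsorted(age, strictly = TRUE))
    stop("ages must be strictly increasing", call. = FALSE)
  if (any(frac <= 0) || any(frac > 1))
    stop("fractions must be in (0, 1]", call. = FALSE)
  if (nrow(tab) == 1) {
    f <- frac[1]
    return(function(x) rep_len(f, length(x)))
  }
  stats::approxfun(age, frac, rule = 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
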