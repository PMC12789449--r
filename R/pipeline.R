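#' Parse an implant STL filename
#'
#' Filenames follow `{block}{position}_{pre|post}.stl`: model (block)
#' number, position letter a-d (case-insensitive), and whether the mesh is
#' the pre-planned or the post-placement implant, e.g. `3b_pre.stl`,
#' `10D_post.stl`.
#'
#' @param filename file name or path.
#' @return A list with `block` (integer), `position` (lower-case letter)
#'   and `phase` (`"pre"` or `"post"`).
#' @export
parse_nomenclature <- function(filename) {
  base <- basename(filename)
  m <- regmatches(base, regexec("^([0-9]+)([a-dA-D])_(pre|post)\\.stl$", base))[[1]]
  if (length(m) == 0) {
    stop("cannot parse \"", base,
         "\": expected {block}{position}_{pre|post}.stl, e.g. 3b_pre.stl",
         call. = FALSE)
  }
  list(block = as.integer(m[2]), position = tolower(m[3]), phase = m[4])
}

#' Discover a study layout on disk
#'
#' Scans `root` for implant STL files following the naming dialect of
#' [parse_nomenclature()] and pairs each pre-planned mesh with its
#' post-placement counterpart. Implants missing either half of the pair are
#' skipped with a warning; a study with no complete pair is an error.
#'
#' @param root directory containing the STL files.
#' @param grouping named vector block -> method id (default:
#'   [default_grouping()] over the blocks found).
#' @return An object of class `study_layout`: data frame with columns
#'   `block`, `position`, `method`, `pre`, `post` (file paths), plus
#'   attribute `root`.
#' @export
study_layout <- function(root, grouping = NULL) {
  if (!dir.exists(root)) stop("no such directory: ", root, call. = FALSE)
  files <- list.files(root, pattern = "\\.stl$", ignore.case = TRUE)
  parsed <- lapply(files, function(f) {
    tryCatch(c(parse_nomenclature(f), path = file.path(root, f)),
             error = function(e) NULL)
  })
  parsed <- parsed[!vapply(parsed, is.null, logical(1))]
  if (length(parsed) == 0) {
    stop("no parseable implant STL files under ", root, call. = FALSE)
  }
  d <- data.frame(
    block = vapply(parsed, function(p) p$block, integer(1)),
    position = vapply(parsed, function(p) p$position, character(1)),
    phase = vapply(parsed, function(p) p$phase, character(1)),
    path = vapply(parsed, function(p) p$path, character(1)),
    stringsAsFactors = FALSE)
  wide <- merge(d[d$phase == "pre", c("block", "position", "path")],
                d[d$phase == "post", c("block", "position", "path")],
                by = c("block", "position"), all = TRUE,
                suffixes = c("_pre", "_post"))
  incomplete <- is.na(wide$path_pre) | is.na(wide$path_post)
  if (any(incomplete)) {
    warning("skipping implants missing a pre or post mesh: ",
            paste(paste0(wide$block, wide$position)[incomplete],
                  collapse = ", "), call. = FALSE)
    wide <- wide[!incomplete, ]
  }
  if (nrow(wide) == 0) stop("no complete pre/post implant pairs", call. = FALSE)
  if (is.null(grouping)) grouping <- default_grouping(unique(wide$block))
  if (!all(as.character(wide$block) %in% names(grouping))) {
    stop("grouping does not cover every block", call. = FALSE)
  }
  wide <- wide[order(wide$block, wide$position), ]
  out <- data.frame(block = wide$block, position = wide$position,
                    method = unname(grouping[as.character(wide$block)]),
                    pre = wide$path_pre, post = wide$path_post,
                    stringsAsFactors = FALSE)
  structure(out, class = c("study_layout", "data.frame"), root = root)
}

#' Measure all planned/placed implant pairs of a study
#'
#' For every pre/post pair in a layout: reads both meshes (assumed already
#' registered into a common frame; see [align_scan()] for aligning whole
#' scans first), extracts both poses with [pose_from_mesh()] — the planned
#' mesh oriented by `pre_hint`, the post-placement mesh by the planned
#' axis, so the 180-degree axis ambiguity cannot corrupt the angle metric —
#' and computes the deviation record.
#'
#' @param layout a [study_layout()].
#' @param spec an [implant_spec()].
#' @param pre_hint approximate coronal-to-apical direction of the planned
#'   implants (default `(0, 0, -1)`, apically downward).
#' @param slab end-slab width for [pose_from_mesh()], mm.
#' @param log optional connection or `""` for progress lines (default
#'   silent).
#' @return A data frame of deviation records (one row per implant) with a
#'   `method` column.
#' @export
measure_study <- function(layout, spec = implant_spec(),
                          pre_hint = c(0, 0, -1), slab = 0.2, log = NULL) {
  stopifnot(inherits(layout, "study_layout"))
  say <- function(...) if (!is.null(log)) cat(sprintf(...), file = log)
  rows <- lapply(seq_len(nrow(layout)), function(i) {
    planned <- pose_from_mesh(read_stl(layout$pre[i]), spec,
                              orientation_hint = pre_hint, slab = slab)
    placed <- pose_from_mesh(read_stl(layout$post[i]), spec,
                             orientation_hint = planned$axis, slab = slab)
    rec <- compare_implants(planned, placed,
                            block = layout$block[i],
                            position = layout$position[i])
    rec$method <- layout$method[i]
    say("measured %s%s: A %.3f mm, B %.3f mm, angle %.3f deg\n",
        layout$block[i], layout$position[i],
        rec$deviation_a, rec$deviation_b, rec$angle_error)
    rec
  })
  do.call(rbind, rows)
}

#' Statistics-only entry point
#'
#' Runs the two-method statistical comparison on an existing per-implant
#' deviation table (the published-table layout) and writes the
#' group-statistics and independent-samples-test CSVs.
#'
#' @param table_csv path to a deviation-table CSV
#'   (see [read_deviation_table()]).
#' @param out_dir output directory.
#' @param grouping,levene_center passed to [build_reports()].
#' @param digits rounding for the written tables (default 2).
#' @return The [build_reports()] result, invisibly.
#' @export
stats_from_table <- function(table_csv, out_dir, grouping = NULL,
                             levene_center = "mean", digits = 2) {
  records <- read_deviation_table(table_csv)
  reports <- build_reports(records, grouping = grouping,
                           levene_center = levene_center)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_group_statistics(reports,
                         file.path(out_dir, "group_statistics.csv"),
                         digits = digits)
  write_independent_samples_test(
    reports, file.path(out_dir, "independent_samples_test.csv"),
    digits = digits)
  invisible(reports)
}

#' Full mesh-to-report pipeline
#'
#' Ties the stages together: discover the study layout under `root`,
#' measure every planned/placed pair, write the per-implant deviation table,
#' run the statistical comparison, and write the two report CSVs. Stage
#' progress and warnings go to stderr and to `run.log` under `out_dir`.
#'
#' @param root directory of implant STL files (see [study_layout()]).
#' @param out_dir output directory.
#' @param spec an [implant_spec()].
#' @param grouping named vector block -> method (default
#'   [default_grouping()]).
#' @param pre_hint,slab passed to [measure_study()].
#' @param levene_center passed to [build_reports()].
#' @param digits rounding for the written report tables.
#' @return A list with `records` (the deviation table) and `reports`
#'   (the `deviation_reports`), invisibly.
#' @export
run_pipeline <- function(root, out_dir, spec = implant_spec(),
                         grouping = NULL, pre_hint = c(0, 0, -1),
                         slab = 0.2, levene_center = "mean", digits = 2) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out_dir, "run.log")
  logcon <- file(logfile, "wt")
  on.exit(close(logcon))
  say <- function(...) {
    msg <- sprintf(...)
    cat(msg, file = stderr())
    cat(msg, file = logcon)
  }
  say("study root: %s\n", root)
  say("config: slab = %.3f mm, levene_center = %s, pre_hint = (%g, %g, %g)\n",
      slab, levene_center, pre_hint[1], pre_hint[2], pre_hint[3])
  layout <- withCallingHandlers(
    study_layout(root, grouping = grouping),
    warning = function(w) {
      say("warning: %s\n", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  say("found %d implant pairs in %d blocks\n",
      nrow(layout), length(unique(layout$block)))
  records <- measure_study(layout, spec = spec, pre_hint = pre_hint,
                           slab = slab, log = logcon)
  table_csv <- file.path(out_dir, "deviation_table.csv")
  write_deviation_table(records, table_csv)
  reports <- build_reports(records, grouping = grouping,
                           levene_center = levene_center)
  write_group_statistics(reports,
                         file.path(out_dir, "group_statistics.csv"),
                         digits = digits)
  write_independent_samples_test(
    reports, file.path(out_dir, "independent_samples_test.csv"),
    digits = digits)
  say("wrote %s, group_statistics.csv, independent_samples_test.csv\n",
      basename(table_csv))
  invisible(list(records = records, reports = reports))
}
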