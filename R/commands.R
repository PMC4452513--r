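# High-level commands backing the command-line script in
# inst/cli/rhizotrack.R. Each is an ordinary function so the whole
# surface stays testable from R.

#' Analyze a series of voxel shape files
#'
#' Reads the shape files (in time order), runs [analyze_series()] and
#' writes the full output bundle.
#'
#' @param files character vector of shape files, ordered by time.
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @return the [analyze_series()] result, invisibly.
#' @export
run_analyze <- function(files, out_dir, config) {
  stopifnot(length(files) >= 1L)
  shapes <- lapply(seq_along(files), function(i) {
    read_voxel_shape(files[[i]], config$edge_length, time_index = i - 1L)
  })
  analysis <- analyze_series(time_series(shapes), config)
  write_analysis(analysis, out_dir)
  invisible(analysis)
}

#' Read branch specs from a YAML file
#'
#' Schema: top-level `edge_length` (mm), `T`, optional `seed_ball`
#' (`radius`, optional `center`), and `branches`, a list of maps with
#' fields `name`, `ctrl` (list of [x, y, z] control points), `radius`,
#' `appear`, `schedule`, and for children `parent` plus `attach_s`.
#'
#' @param path YAML file.
#' @return list with `specs`, `T`, `edge_length`, `seed_ball_radius`,
#'   `seed_ball_center`.
#' @export
read_spec_file <- function(path) {
  y <- yaml::read_yaml(path)
  for (field in c("edge_length", "T", "branches")) {
    if (is.null(y[[field]])) stop("spec file: missing field '", field, "'")
  }
  specs <- lapply(seq_along(y$branches), function(i) {
    b <- y$branches[[i]]
    for (field in c("name", "ctrl", "radius", "schedule")) {
      if (is.null(b[[field]])) {
        stop(sprintf("spec file: branches[%d]: missing field '%s'", i, field))
      }
    }
    ctrl <- do.call(rbind, lapply(b$ctrl, as.numeric))
    branch_spec(b$name, ctrl, radius = b$radius,
                appear = b$appear %||% 0L,
                schedule = as.numeric(b$schedule),
                parent = b$parent, attach_s = b$attach_s)
  })
  list(specs = specs, T = as.integer(y$T), edge_length = y$edge_length,
       seed_ball_radius = y$seed_ball$radius,
       seed_ball_center = if (!is.null(y$seed_ball$center))
         as.numeric(y$seed_ball$center) else NULL)
}

#' Generate a synthetic series from a spec file and write it out
#'
#' Writes one voxel file per timepoint (text dialect), the ground-truth
#' table (TSV) and the true motions.
#'
#' @param spec_file YAML branch spec file (see [read_spec_file()]).
#' @param out_dir output directory.
#' @param perturb,seed passed to [generate_series()].
#' @return the [generate_series()] result, invisibly.
#' @export
run_simulate <- function(spec_file, out_dir, perturb = FALSE, seed = 1L) {
  sp <- read_spec_file(spec_file)
  gen <- generate_series(sp$specs, T = sp$T, edge_length = sp$edge_length,
                         seed_ball_radius = sp$seed_ball_radius,
                         seed_ball_center = sp$seed_ball_center,
                         perturb = perturb, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (t in 0:gen$series$T) {
    write_voxel_shape(gen$series$shapes[[t + 1L]],
                      file.path(out_dir, sprintf("shape_t%02d.txt", t)))
  }
  write.table(gen$truth, file.path(out_dir, "ground_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (t in 0:gen$series$T) {
    m <- gen$motions[[t + 1L]]
    writeLines(paste(format(c(t(m$R), m$t), digits = 17), collapse = " "),
               file.path(out_dir, sprintf("true_motion_t%02d.txt", t)))
  }
  invisible(gen)
}

#' Compare a written trait table against a written ground-truth table
#'
#' @param traits_file `traits_long.tsv` from [run_analyze()].
#' @param truth_file `ground_truth.tsv` from [run_simulate()].
#' @return the [evaluate_against_truth()] report.
#' @export
run_validate <- function(traits_file, truth_file) {
  traits <- read.table(traits_file, header = TRUE, sep = "\t")
  truth <- read.table(truth_file, header = TRUE, sep = "\t")
  need <- c("branch", "t", "length", "volume_mm3", "tortuosity",
            "tip_x", "tip_y", "tip_z")
  if (!all(need %in% names(truth))) {
    stop("truth table: missing column(s): ",
         paste(setdiff(need, names(truth)), collapse = ", "))
  }
  evaluate_against_truth(traits, truth)
}

#' Convert a voxel file between the text and volume dialects
#'
#' @param in_file,out_file input and output paths; the dialect of each is
#'   chosen from its extension (`.nii`/`.nii.gz` = dense volume mask,
#'   otherwise text triples).
#' @param edge_length voxel edge in mm.
#' @return `out_file`, invisibly.
#' @export
convert_voxel_file <- function(in_file, out_file, edge_length) {
  write_voxel_shape(read_voxel_shape(in_file, edge_length), out_file)
  invisible(out_file)
}
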