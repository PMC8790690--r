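#' Run the full evaluation pipeline
#'
#' Orchestrates the whole analysis for a survey file or dataset: ingest,
#' optional respondent split into test/validation groups (or use of an
#' explicit group column), per-group fitting, ranking from the chosen
#' corner, between-group comparison, and CSV export. Each written table
#' mirrors the conventional report layout: a counts table (M, P, A, I, R,
#' Q, Category per attribute), an index table (Better/Worse, importance,
#' weighted values), a ranking table (d, alpha, f, rank — rounded, plus a
#' `*_full` machine-readable variant at full precision) and quadrant-plot
#' data (attribute, |worse|, better, quadrant).
#'
#' @param data A [kano_survey], or a path to a long-format CSV.
#' @param output_dir Directory for the report bundle; created if needed.
#'   `NULL` skips writing and just returns the bundle.
#' @param split Either a list `list(fraction =, seed =)` to split
#'   respondents randomly, the name of a strata column holding explicit
#'   group labels, or `NULL` to analyse the panel as one group.
#' @param pov Corner point of view for the rankings (see [corner_pov()]).
#' @param schema,layout Passed to [read_survey()] when `data` is a path.
#' @param importance_map See [kano_importance_map()].
#' @param digits Reporting precision for the rounded tables.
#' @return Invisibly, a list with per-group `fits` (class `kano`),
#'   `rankings`, `indices`, `counts`, `plot_data`, the between-group
#'   `comparison` (coordinate distances and a chi-square test on the
#'   category counts, when exactly two groups), and `log` (seed, sizes,
#'   file names).
#' @examples
#' prof <- profile_from_counts(
#'   kano_counts("practicality", c(M = 127, P = 42, A = 10, I = 7)), 0.88)
#' s <- generate_survey(list(prof), n_respondents = 60, seed = 1)
#' res <- run_pipeline(s, output_dir = NULL, split = list(fraction = 0.5, seed = 2))
#' names(res$fits)
#' @export
run_pipeline <- function(data, output_dir = NULL, split = NULL,
                         pov = "must-be", schema = list(), layout = "long",
                         importance_map = kano_importance_map(), digits = 2) {
  if (is.character(data) && length(data) == 1L) {
    data <- read_survey(data, schema = schema, layout = layout)
  }
  if (!inherits(data, "kano_survey")) data <- kano_survey(data)
  pov <- as_corner_pov(pov)

  groups <- if (is.null(split)) {
    list(all = data)
  } else if (is.list(split)) {
    split_groups(data, fraction = split$fraction %||% 0.5, seed = split$seed)
  } else if (is.character(split) && length(split) == 1L) {
    stratify(data, split)
  } else {
    stop("'split' must be NULL, a list(fraction, seed), or a column name",
         call. = FALSE)
  }

  fits <- lapply(groups, kano, importance_map = importance_map)
  rankings <- lapply(fits, function(f) rank_attributes(kano_coordinates(f), pov))
  indices <- lapply(fits, function(f) f$table[c("attribute", "better", "worse",
                                                "importance", "better_weighted",
                                                "worse_weighted")])
  counts <- lapply(fits, function(f) f$table[c("attribute", kano_categories(),
                                               "n_complete", "n_missing",
                                               "category", "category_ifthen")])
  plot_data <- lapply(fits, function(f) {
    co <- kano_coordinates(f)
    data.frame(attribute = co$attribute, worse_abs = abs(co$worse),
               better = co$better,
               quadrant = quadrant_of(co$worse, co$better),
               stringsAsFactors = FALSE)
  })

  comparison <- NULL
  if (length(fits) == 2L) {
    a <- kano_coordinates(fits[[1L]]); b <- kano_coordinates(fits[[2L]])
    b <- b[match(a$attribute, b$attribute), ]
    comparison <- list(
      coordinate_distance = data.frame(
        attribute = a$attribute,
        distance = between_group_distance(a$worse, a$better, b$worse, b$better),
        stringsAsFactors = FALSE),
      category_chisq = tryCatch({
        m <- rbind(colSums(fits[[1L]]$table[kano_categories()]),
                   colSums(fits[[2L]]$table[kano_categories()]))
        m <- m[, colSums(m) > 0, drop = FALSE]
        suppressWarnings(compare_counts(m))
      }, error = function(e) NULL))
  }

  log <- list(package_version = as.character(utils::packageVersion("kanosight")),
              n_respondents = vapply(groups, n_respondents, integer(1)),
              attributes = survey_attributes(data), pov = pov$name,
              split = if (is.list(split)) split else list(column = split))

  bundle <- list(fits = fits, rankings = rankings, indices = indices,
                 counts = counts, plot_data = plot_data,
                 comparison = comparison, log = log)
  if (!is.null(output_dir)) write_bundle(bundle, output_dir, digits)
  invisible(bundle)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_bundle <- function(bundle, output_dir, digits = 2) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  wr <- function(df, name) {
    path <- file.path(output_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, name)
  }
  for (g in names(bundle$fits)) {
    wr(bundle$counts[[g]], sprintf("counts_%s.csv", g))
    ind <- bundle$indices[[g]]
    ind[-1L] <- lapply(ind[-1L], round_half_up, digits = digits)
    wr(ind, sprintf("indices_%s.csv", g))
    rk <- as.data.frame(bundle$rankings[[g]])
    full <- rk[c("attribute", "worse", "better", "distance", "angle",
                 "coefficient", "rank")]
    wr(full, sprintf("ranking_%s_full.csv", g))
    rk$distance <- round_half_up(rk$distance, digits)
    rk$angle <- round_half_up(rk$angle, 0)
    rk$coefficient <- round_half_up(rk$coefficient, digits)
    wr(rk[c("attribute", "distance", "angle", "coefficient", "rank")],
       sprintf("ranking_%s.csv", g))
    wr(bundle$plot_data[[g]], sprintf("quadrant_%s.csv", g))
  }
  if (!is.null(bundle$comparison)) {
    wr(bundle$comparison$coordinate_distance, "coordinate_distance.csv")
    if (!is.null(bundle$comparison$category_chisq)) {
      cc <- bundle$comparison$category_chisq
      wr(data.frame(statistic = cc$statistic, dof = cc$dof, p_value = cc$p_value),
         "category_chisq.csv")
    }
  }
  log <- bundle$log
  log_lines <- c(sprintf("package_version = %s", log$package_version),
                 sprintf("pov = %s", log$pov),
                 sprintf("group_%s_n = %d", names(log$n_respondents),
                         log$n_respondents),
                 sprintf("attributes = %s", paste(log$attributes, collapse = ",")),
                 sprintf("file = %s", files))
  writeLines(log_lines, file.path(output_dir, "run_log.txt"))
  invisible(output_dir)
}

#' Export the quadrant chart with its data twin
#'
#' Writes the Better-Worse quadrant chart as PNG or SVG together with a
#' CSV "data twin" holding the exact plotted numbers (attribute,
#' |worse|, better, quadrant and, when arrows are drawn, the unweighted
#' start coordinates). Re-reading the twin and re-ranking reproduces the
#' pipeline's ranking at full precision.
#'
#' @param fit A `kano` fit.
#' @param file Image path ending in `.png` or `.svg`.
#' @param annotate_importance_shift Draw unweighted-to-weighted arrows and
#'   include the shift columns in the data twin.
#' @param weighted Plot weighted coordinates (default).
#' @return Invisibly, the data twin data.frame; the CSV lands next to
#'   `file` with extension `.csv`.
#' @export
export_quadrant_plot <- function(fit, file, annotate_importance_shift = FALSE,
                                 weighted = TRUE) {
  stopifnot(inherits(fit, "kano"))
  ext <- tolower(tools::file_ext(file))
  dev <- switch(ext, png = grDevices::png, svg = grDevices::svg,
                stop("'file' must end in .png or .svg", call. = FALSE))
  if (ext == "png") dev(file, width = 1200, height = 1200, res = 150)
  else dev(file, width = 7, height = 7)
  plot(fit, weighted = weighted,
       annotate_importance_shift = annotate_importance_shift)
  grDevices::dev.off()
  co <- kano_coordinates(fit, weighted = weighted)
  twin <- data.frame(attribute = co$attribute, worse = co$worse,
                     worse_abs = abs(co$worse), better = co$better,
                     quadrant = quadrant_of(co$worse, co$better),
                     stringsAsFactors = FALSE)
  if (annotate_importance_shift && weighted) {
    raw <- kano_coordinates(fit, weighted = FALSE)
    twin$worse_unweighted <- raw$worse
    twin$better_unweighted <- raw$better
  }
  csv <- paste0(tools::file_path_sans_ext(file), ".csv")
  utils::write.csv(twin, csv, row.names = FALSE)
  invisible(twin)
}

#' Read a plain-text key-value configuration file
#'
#' Minimal `key = value` format for pipeline configuration: one setting
#' per line, `#` comments, values split on commas into vectors, numbers
#' auto-converted. Understood keys match [run_pipeline()] arguments
#' (`input`, `pov`, `fraction`, `seed`, `output_dir`, plus `schema.*`
#' entries forming the schema list).
#'
#' @param path Config file path.
#' @return Named list of settings (with a nested `schema` list).
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(m[2L]); val <- trimws(m[3L])
    val <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(val))
    if (!anyNA(num)) val <- num
    if (startsWith(key, "schema.")) {
      out$schema[[sub("^schema\\.", "", key)]] <- val
    } else {
      out[[key]] <- val
    }
  }
  out
}
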