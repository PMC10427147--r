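# Delimited-text file formats, configuration, and the end-to-end pipeline.
# The native interchange format is TSV/CSV: portable, diffable, and lossless
# at stated tolerances. Vertex ids are 0-based in files.

SUBJECT_COLUMNS <- c(
  "vertex_id", "x", "y", "hemisphere", "roi_label",
  "polar_angle_deg", "eccentricity_deg", "curvature", "mean_bold",
  "fit2_polar_deg", "fit3_polar_deg", "fit2_ecc_deg", "fit3_ecc_deg"
)

#' Write one subject-hemisphere record to a TSV file
#'
#' @param record list with `map`, `fit2`, `fit3` ([retino_map] objects, as in
#'   a `retino_population` subject entry).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(record, path) {
  map <- record$map
  stopifnot(inherits(map, "retino_map"))
  df <- data.frame(
    vertex_id = map$patch$vertex_id,
    x = map$patch$x,
    y = map$patch$y,
    hemisphere = map$hemisphere,
    roi_label = map$patch$roi_label,
    polar_angle_deg = map$polar_angle,
    eccentricity_deg = map$eccentricity,
    curvature = map$curvature %||% NA_real_,
    mean_bold = map$mean_bold %||% NA_real_,
    fit2_polar_deg = record$fit2$polar_angle,
    fit3_polar_deg = record$fit3$polar_angle,
    fit2_ecc_deg = record$fit2$eccentricity,
    fit3_ecc_deg = record$fit3$eccentricity
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a subject-hemisphere TSV file
#'
#' Validates the header, the absence of missing values in required fields,
#' the polar-angle range and eccentricity sign, naming the offending
#' row/column on failure. Extra columns are ignored with a warning.
#'
#' @param path TSV file written by [write_subject_table()].
#' @return list with `patch`, `map`, `fit2`, `fit3`.
#' @export
read_subject_table <- function(path) {
  if (!file.exists(path)) stop_nf("read_subject_table: no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(SUBJECT_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop_nf("read_subject_table: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(df), SUBJECT_COLUMNS)
  if (length(extra)) {
    warning("read_subject_table: ignoring extra column(s): ", paste(extra, collapse = ", "))
    df <- df[SUBJECT_COLUMNS]
  }
  required <- setdiff(SUBJECT_COLUMNS, c("curvature", "mean_bold"))
  for (cl in required) {
    bad <- which(is.na(df[[cl]]))
    if (length(bad)) {
      stop_nf("read_subject_table: missing value in column '", cl, "', row ", bad[1])
    }
  }
  for (cl in grep("polar", names(df), value = TRUE)) {
    bad <- which(df[[cl]] < 0 | df[[cl]] >= 360)
    if (length(bad)) {
      stop_nf("read_subject_table: out-of-range angle in column '", cl, "', row ", bad[1])
    }
  }
  for (cl in grep("ecc", names(df), value = TRUE)) {
    bad <- which(df[[cl]] < 0)
    if (length(bad)) {
      stop_nf("read_subject_table: negative eccentricity in column '", cl, "', row ", bad[1])
    }
  }
  hemi <- unique(df$hemisphere)
  if (length(hemi) != 1 || !hemi %in% c("left", "right")) {
    stop_nf("read_subject_table: hemisphere column must be a single 'left'/'right' value")
  }
  patch <- data.frame(
    vertex_id = as.integer(df$vertex_id),
    x = df$x, y = df$y, roi_label = df$roi_label,
    stringsAsFactors = FALSE
  )
  attr(patch, "hemisphere") <- hemi
  class(patch) <- c("flat_patch", "data.frame")
  curv <- if (all(is.na(df$curvature))) NULL else df$curvature
  bold <- if (all(is.na(df$mean_bold))) NULL else df$mean_bold
  list(
    patch = patch,
    map = retino_map(patch, df$polar_angle_deg, df$eccentricity_deg,
      curvature = curv, mean_bold = bold),
    fit2 = retino_map(patch, df$fit2_polar_deg, df$fit2_ecc_deg,
      curvature = curv, mean_bold = bold),
    fit3 = retino_map(patch, df$fit3_polar_deg, df$fit3_ecc_deg,
      curvature = curv, mean_bold = bold)
  )
}

#' Write / read a similarity matrix as TSV
#'
#' Full-precision delimited text with subject ids as header row and first
#' column; `read_matrix(write_matrix(S)) == S` to 1e-12.
#'
#' @param s symmetric similarity matrix.
#' @param path file path.
#' @return `path` invisibly (write); the matrix (read).
#' @export
write_matrix <- function(s, path) {
  validate_similarity(s)
  ids <- rownames(s) %||% sprintf("sub%03d", seq_len(nrow(s)))
  df <- data.frame(subject_id = ids, s, check.names = FALSE)
  colnames(df) <- c("subject_id", ids)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop_nf("read_matrix: no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "subject_id") stop_nf("read_matrix: malformed header")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) != ncol(m)) stop_nf("read_matrix: matrix is not square")
  storage.mode(m) <- "double"
  dimnames(m) <- list(df$subject_id, colnames(df)[-1])
  m
}

PIPELINE_DEFAULTS <- list(
  n_subjects = 24, n_vertices = 3000, seed = 1,
  proportions_canonical = 1 / 3, proportions_fork = 1 / 3, proportions_truncated = 1 / 3,
  hemisphere_noise_ratio = 1.22, portion_noise_ratio = 1.22,
  base_polar_sd = 10,
  mask_lo = 1, mask_hi = 8,
  discretization = "polar",
  k = 6, cluster_seed = 1,
  grid_nx = 200, grid_ny = 200,
  covariates = 1
)

#' Read / write a flat key-value pipeline configuration
#'
#' Lines of the form `key = value`; `#` starts a comment. Unknown keys are an
#' error; missing keys take the documented defaults (eccentricity mask 1-8
#' degrees, k = 6 with a fixed clustering seed, 200x200 field-sign grid).
#'
#' @param path config file path.
#' @return named list of settings.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_nf("read_config: no such file: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- PIPELINE_DEFAULTS
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop_nf("read_config: malformed line: '", ln, "'")
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    if (!key %in% names(PIPELINE_DEFAULTS)) stop_nf("read_config: unknown key: '", key, "'")
    cfg[[key]] <- if (key == "discretization") val else as.numeric(val)
  }
  cfg
}

#' @rdname read_config
#' @param cfg named list of settings.
#' @export
write_config <- function(cfg, path) {
  writeLines(
    vapply(names(cfg), function(k) paste(k, "=", format(cfg[[k]], digits = 17)),
      character(1)),
    path
  )
  invisible(path)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_nf("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' simulate -> variability table -> similarity -> clustering -> field sign ->
#' mixed model, writing every stage output under `out_dir` plus a JSON run
#' manifest. All stages are deterministic given the config seeds, so a rerun
#' reproduces the outputs byte-identically.
#'
#' Stage outputs: per-subject TSVs and `population_manifest.csv`;
#' `variability_long.csv`; `similarity.tsv`; `clusters.csv`;
#' `fieldsign_scores.csv`; `fieldsign_grid_sub001_left.tsv` (example grid);
#' `lme_polar.csv` / `lme_eccentricity.csv`; `run_manifest.json`.
#'
#' @param config named list (see [read_config()]) or a path to a config file.
#' @param out_dir output directory, created if needed.
#' @return the run manifest, invisibly (list; also written as JSON).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  t0 <- Sys.time()

  pop <- pipeline_stage("simulate", {
    patch <- make_flat_patch(cfg$n_vertices, "left", seed = cfg$seed)
    spec <- population_spec(
      n_subjects = cfg$n_subjects,
      variant_proportions = c(
        canonical = cfg$proportions_canonical,
        fork = cfg$proportions_fork,
        truncated = cfg$proportions_truncated
      ),
      hemisphere_noise_ratio = cfg$hemisphere_noise_ratio,
      portion_noise_ratio = cfg$portion_noise_ratio,
      base_polar_sd = cfg$base_polar_sd,
      seed = cfg$seed
    )
    pop <- simulate_population(spec, patch)
    for (i in seq_along(pop$subjects)) {
      for (h in c("left", "right")) {
        f <- file.path(out_dir, sprintf("%s_%s.tsv", pop$manifest$subject_id[i], h))
        write_subject_table(pop$subjects[[i]]$hemis[[h]], f)
        files <- c(files, f)
      }
    }
    f <- file.path(out_dir, "population_manifest.csv")
    utils::write.csv(pop$manifest, f, row.names = FALSE)
    files <- c(files, f)
    pop
  })

  records <- pipeline_stage("variability", {
    rec <- variability_records(pop, lo = cfg$mask_lo, hi = cfg$mask_hi)
    f <- file.path(out_dir, "variability_long.csv")
    utils::write.csv(rec, f, row.names = FALSE)
    files <- c(files, f)
    rec
  })

  s <- pipeline_stage("similarity", {
    maps <- population_maps(pop, "left", "map")
    dmaps <- if (identical(cfg$discretization, "eccentricity")) {
      lapply(maps, discretize_eccentricity)
    } else {
      lapply(maps, discretize_polar)
    }
    s <- pairwise_similarity(dmaps)
    f <- file.path(out_dir, "similarity.tsv")
    write_matrix(s, f)
    files <- c(files, f)
    s
  })

  cl <- pipeline_stage("cluster", {
    cl <- spectral_cluster(s, k = cfg$k, seed = cfg$cluster_seed)
    wb <- within_between_summary(s, cl)
    f <- file.path(out_dir, "clusters.csv")
    utils::write.csv(
      data.frame(subject_id = names(cl$assignment), cluster_id = unname(cl$assignment)),
      f, row.names = FALSE
    )
    files <- c(files, f)
    attr(cl, "within_between") <- wb
    cl
  })

  pipeline_stage("fieldsign", {
    scores <- NULL
    grid_written <- FALSE
    for (i in seq_along(pop$subjects)) {
      map <- pop$subjects[[i]]$hemis$left$map
      fs <- visual_field_sign(map, nx = cfg$grid_nx, ny = cfg$grid_ny)
      v3d <- grid_roi_mask(map$patch, "V3d", fs)
      sc <- v3d_discontinuity_score(fs, v3d)
      scores <- rbind(scores, data.frame(
        subject_id = pop$manifest$subject_id[i],
        true_variant = pop$manifest$true_variant[i],
        v3d_score = sc$score,
        discontinuous = sc$discontinuous
      ))
      if (!grid_written) {
        gf <- file.path(out_dir, sprintf("fieldsign_grid_%s_left.tsv",
          pop$manifest$subject_id[i]))
        grid_df <- expand.grid(x = fs$x, y = fs$y)
        grid_df$sign <- as.vector(fs$sign)
        grid_df$valid <- !is.na(as.vector(fs$sign))
        utils::write.table(grid_df, gf, sep = "\t", quote = FALSE, row.names = FALSE)
        files <- c(files, gf)
        grid_written <- TRUE
      }
    }
    f <- file.path(out_dir, "fieldsign_scores.csv")
    utils::write.csv(scores, f, row.names = FALSE)
    files <- c(files, f)
  })

  pipeline_stage("lme", {
    for (resp in c("polar", "eccentricity")) {
      tab <- build_long_table(records, response = resp, covariates = cfg$covariates > 0)
      fit <- fit_lme(tab, covariates = cfg$covariates > 0)
      f <- file.path(out_dir, paste0("lme_", resp, ".csv"))
      if (fit$converged) {
        utils::write.csv(fit$coefficients, f, row.names = FALSE)
      } else {
        utils::write.csv(data.frame(effect = "NOT CONVERGED"), f, row.names = FALSE)
      }
      files <- c(files, f)
    }
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("retinovar")),
    config = cfg,
    seeds = list(simulate = cfg$seed, cluster = cfg$cluster_seed),
    outputs = sort(basename(files)),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
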