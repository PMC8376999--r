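# Cohort-level orchestration: simulate -> extract ROI -> detect -> enroll ->
# identify -> evaluate, plus the file formats of every artifact.

#' Extract dot patterns for a set of cohort images
#'
#' Renders each image, runs the ROI pipeline and the chosen dot detector.
#'
#' @param cohort A [generate_cohort()] object.
#' @param image_ids Manifest image ids (default: all).
#' @param detector `"blob"` (deterministic, training-free) or `"cnn"`.
#' @param classifier Required for `detector = "cnn"`.
#' @param config [roi_config()].
#' @param verbose Print progress every 100 images.
#' @return Named list (by image id) of [dot_pattern()]s.
#' @export
cohort_patterns <- function(cohort, image_ids = cohort$manifest$image_id,
                            detector = c("blob", "cnn"), classifier = NULL,
                            config = roi_config(), verbose = FALSE) {
  detector <- match.arg(detector)
  if (detector == "cnn" && is.null(classifier))
    stop("detector = \"cnn\" needs a trained classifier")
  out <- vector("list", length(image_ids))
  names(out) <- as.character(image_ids)
  for (k in seq_along(image_ids)) {
    id <- image_ids[k]
    row <- cohort$manifest[cohort$manifest$image_id == id, ]
    fi <- render_cohort_image(cohort, id)
    roi <- extract_normalized_roi(fi, config)
    out[[k]] <- if (detector == "blob")
      detect_dots_blob(roi, image_id = id, fish_id = row$fish_id,
                       session = row$session)
    else
      detect_dots(roi, classifier, image_id = id, fish_id = row$fish_id,
                  session = row$session)
    if (verbose && k %% 100 == 0)
      message("  patterns: ", k, "/", length(image_ids))
  }
  out
}

#' Run the short-term identification experiment
#'
#' Emulates the pattern-uniqueness test: per fish, one image is the query
#' and `n_templates` further images are enrolled; every query is identified
#' against the full gallery by nearest-neighbour trimmed-distance matching.
#'
#' @param patterns Named list of per-image [dot_pattern()]s (e.g. from
#'   [cohort_patterns()]) carrying `fish_id`.
#' @param config [match_config()].
#' @param n_templates Templates per fish.
#' @return List: `results` data frame (query_id, true_id, predicted_id,
#'   distance), `report` ([identification_accuracy()]), `gallery`.
#' @export
run_short_term <- function(patterns, config = match_config(),
                           n_templates = 2) {
  fids <- vapply(patterns, function(p) as.character(p$fish_id), "")
  by_fish <- split(patterns, fids)
  gallery <- lapply(by_fish, function(ps) ps[seq(2, min(1 + n_templates,
                                                        length(ps)))])
  queries <- lapply(by_fish, `[[`, 1)
  rows <- lapply(names(queries), function(fid) {
    r <- identify_short_term(queries[[fid]], gallery, config)
    bs <- r$best_shifts[which(names(r$distances) == r$predicted_id), ]
    data.frame(query_id = queries[[fid]]$image_id, true_id = fid,
               predicted_id = r$predicted_id,
               distance = min(r$distances),
               dx = bs[1], dy = bs[2], stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  list(results = results, report = identification_accuracy(results),
       gallery = gallery)
}

#' Run the long-term identification experiment
#'
#' Builds one representative pattern per fish and session, then identifies
#' every fish of every session against the gallery of every other session
#' (all ordered session pairs).
#'
#' @param patterns Named list of per-image [dot_pattern()]s carrying
#'   `fish_id` and `session`.
#' @param config [match_config()] for the long-term matching (50-px shifts).
#' @param align_config [match_config()] used when building representatives.
#' @param accept_dist Support radius of [build_representative()].
#' @return List: `results` data frame with `session_pair`, `report`, and the
#'   `representatives` (fish -> session -> pattern).
#' @export
run_long_term <- function(patterns, config = match_config(max_shift = 50),
                          align_config = match_config(),
                          accept_dist = 20) {
  fids <- vapply(patterns, function(p) as.character(p$fish_id), "")
  sess <- vapply(patterns, function(p) as.character(p$session), "")
  sessions <- unique(sess)
  reps <- list()
  for (s in sessions) {
    sel <- patterns[sess == s]
    reps[[s]] <- lapply(split(sel, fids[sess == s]), build_representative,
                        config = align_config, accept_dist = accept_dist)
  }
  rows <- list(); k <- 0
  for (sa in sessions) for (sb in sessions) {
    if (sa == sb) next
    gallery <- reps[[sb]]
    for (fid in names(reps[[sa]])) {
      r <- identify_long_term(reps[[sa]][[fid]], gallery, config)
      bs <- r$best_shifts[which(names(r$distances) == r$predicted_id), ]
      k <- k + 1
      rows[[k]] <- data.frame(session_pair = paste(sa, sb, sep = "/"),
                              true_id = fid, predicted_id = r$predicted_id,
                              distance = min(r$distances),
                              dx = bs[1], dy = bs[2],
                              stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  list(results = results, report = identification_accuracy(results),
       representatives = reps)
}

#' Run a HOG-based identification experiment
#'
#' The texture-descriptor route: per image the normalized ROI is extracted;
#' for a single session the first image of every fish is the unknown and the
#' next `n_templates` images are the known images; across sessions, all
#' images of a fish in one session are matched against all of its images in
#' the other (best similarity over all combinations and scan placements).
#'
#' @param cohort A [generate_cohort()] object.
#' @param config [hog_config()]; the default uses a coarser scan stride than
#'   the per-image default, appropriate for cohort-level runs.
#' @param roi_conf [roi_config()].
#' @param n_templates Known images per fish in the single-session design.
#' @return List with `results` and `report`, as [run_short_term()].
#' @export
run_hog_experiment <- function(cohort, config = hog_config(scan_stride = 12),
                               roi_conf = roi_config(), n_templates = 2) {
  man <- cohort$manifest
  rois <- lapply(man$image_id, function(i)
    extract_normalized_roi(render_cohort_image(cohort, i), roi_conf))
  names(rois) <- as.character(man$image_id)
  sessions <- unique(man$session)
  rows <- list(); k <- 0
  if (length(sessions) == 1) {
    known <- man$image_index > 1 & man$image_index <= 1 + n_templates
    gallery <- lapply(split(man$image_id[known], man$fish_id[known]),
                      function(ii) rois[as.character(ii)])
    for (fid in unique(man$fish_id)) {
      sel <- man$image_id[man$fish_id == fid]
      r <- identify_hog(rois[[as.character(sel[1])]], gallery, config)
      k <- k + 1
      rows[[k]] <- data.frame(query_id = sel[1], true_id = as.character(fid),
                              predicted_id = r$predicted_id,
                              distance = min(r$distances),
                              stringsAsFactors = FALSE)
    }
  } else {
    for (sa in sessions) for (sb in sessions) {
      if (sa == sb) next
      gallery <- lapply(split(man$image_id[man$session == sb],
                              man$fish_id[man$session == sb]),
                        function(ii) rois[as.character(ii)])
      for (fid in unique(man$fish_id)) {
        qs <- rois[as.character(man$image_id[man$session == sa &
                                               man$fish_id == fid])]
        r <- identify_hog(qs, gallery, config)
        k <- k + 1
        rows[[k]] <- data.frame(session_pair = paste(sa, sb, sep = "/"),
                                true_id = as.character(fid),
                                predicted_id = r$predicted_id,
                                distance = min(r$distances),
                                stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  list(results = results, report = identification_accuracy(results))
}

## ---- serialization ---------------------------------------------------------

#' Write dot patterns to CSV
#'
#' Long format: one row per dot with image_id, fish_id, session, x, y.
#'
#' @param patterns List of [dot_pattern()]s.
#' @param path Output CSV.
#' @export
write_patterns <- function(patterns, path) {
  rows <- lapply(patterns, function(p) {
    if (nrow(p$points) == 0) return(NULL)
    data.frame(image_id = p$image_id, fish_id = p$fish_id,
               session = p$session, x = p$points[, 1], y = p$points[, 2])
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read dot patterns from CSV
#'
#' @param path CSV written by [write_patterns()].
#' @return Named list of [dot_pattern()]s keyed by image id.
#' @export
read_patterns <- function(path) {
  df <- read.csv(path)
  lapply(split(df, df$image_id), function(d)
    dot_pattern(cbind(d$x, d$y), image_id = d$image_id[1],
                fish_id = d$fish_id[1], session = d$session[1]))
}

#' Write an enrollment gallery to JSON
#'
#' @param gallery Named list fish id -> [dot_pattern()] (or list of them).
#' @param path Output JSON.
#' @export
write_gallery <- function(gallery, path) {
  enc <- function(p) list(session = p$session,
                          points = unname(as.matrix(p$points)),
                          support = p$support %||% NULL)
  obj <- lapply(gallery, function(g) {
    if (inherits(g, "dot_pattern")) enc(g) else lapply(g, enc)
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an enrollment gallery from JSON
#'
#' @param path JSON written by [write_gallery()].
#' @return Named list fish id -> pattern or list of patterns.
#' @export
read_gallery <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- function(e, fid) {
    p <- dot_pattern(e$points, fish_id = fid, session = e$session %||% NA)
    if (!is.null(e$support)) {
      p$support <- e$support
      p$n_source_patterns <- NA_integer_
      class(p) <- c("representative_pattern", "dot_pattern")
    }
    p
  }
  out <- lapply(names(obj), function(fid) {
    e <- obj[[fid]]
    if (!is.null(e$points)) dec(e, fid) else lapply(e, dec, fid = fid)
  })
  names(out) <- names(obj)
  out
}

## ---- end-to-end pipeline ---------------------------------------------------

#' Pipeline configuration
#'
#' Collects every stage's settings in one list that round-trips losslessly
#' through YAML. All stochastic stages read their seed from here.
#'
#' @param seed Master seed.
#' @param n_fish,images_per_fish,n_sessions,n_dots_range Cohort settings.
#' @param detector `"blob"` or `"cnn"`.
#' @param matcher `"dot"` or `"hog"`.
#' @param n_patches_per_class Training-set size for the cnn detector.
#' @param ... Overrides stored verbatim (e.g. `max_shift`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, n_fish = 10, images_per_fish = 3,
                            n_sessions = 1, n_dots_range = c(8, 30),
                            detector = "blob", matcher = "dot",
                            n_patches_per_class = 150, ...) {
  cfg <- c(list(seed = seed, n_fish = n_fish,
                images_per_fish = images_per_fish, n_sessions = n_sessions,
                n_dots_range = n_dots_range, detector = detector,
                matcher = matcher,
                n_patches_per_class = n_patches_per_class),
           list(...))
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  s <- yaml::as.yaml(unclass(cfg))
  # small rolling hash; enough to detect configuration drift in logs
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 1e9
}

#' Run the identification pipeline
#'
#' Executes the requested stages in order, writing each stage's artifacts under
#' `dir` and logging the parameters actually used. Stages: `simulate`
#' (cohort manifest), `train-detector` (only for the cnn detector),
#' `detect` (patterns.csv), `enroll` (gallery.json), `identify`
#' (results.csv), `evaluate` (report.json). Rerunning a stage with the same
#' config reproduces its outputs byte for byte.
#'
#' @param config [pipeline_config()] or path to a YAML file of one.
#' @param dir Artifact directory.
#' @param stages Character vector of stages (default: all applicable).
#' @return Invisible list of in-memory stage outputs.
#' @export
run_pipeline <- function(config = pipeline_config(), dir = tempfile("finprint"),
                         stages = c("simulate", "train-detector", "detect",
                                    "enroll", "identify", "evaluate")) {
  if (is.character(config)) {
    cfg <- yaml::read_yaml(config)
    class(cfg) <- "pipeline_config"
  } else cfg <- config
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  logmsg <- function(...) message("[finprint ", config_hash(cfg), "] ", ...)
  out <- list()

  cohort <- NULL
  get_cohort <- function() {
    if (is.null(cohort))
      cohort <<- generate_cohort(
        cfg$n_fish, cfg$images_per_fish,
        sessions = session_templates(cfg$n_sessions),
        seed = cfg$seed, n_dots_range = cfg$n_dots_range)
    cohort
  }

  if ("simulate" %in% stages) {
    logmsg("simulate: n_fish=", cfg$n_fish, " images_per_fish=",
        cfg$images_per_fish, " sessions=", cfg$n_sessions,
        " seed=", cfg$seed)
    write.csv(get_cohort()$manifest, file.path(dir, "manifest.csv"),
              row.names = FALSE)
    out$cohort <- get_cohort()
  }

  classifier <- NULL
  if ("train-detector" %in% stages && identical(cfg$detector, "cnn")) {
    logmsg("train-detector: n_per_class=", cfg$n_patches_per_class,
        " seed=", cfg$seed)
    ds <- generate_patches(cfg$n_patches_per_class, seed = cfg$seed,
                           near_dot_fraction = 0.15)
    classifier <- train_patch_classifier(ds, seed = cfg$seed)
    saveRDS(classifier, file.path(dir, "detector.rds"))
    jsonlite::write_json(
      list(architecture = "conv3x3-8/16/32 + fc64 + softmax2",
           seed = cfg$seed, n_train = sum(ds$split == "train"),
           test_accuracy = classifier$test_accuracy),
      file.path(dir, "detector.json"), auto_unbox = TRUE)
    out$classifier <- classifier
  }

  patterns <- NULL
  if ("detect" %in% stages) {
    if (identical(cfg$detector, "cnn") && is.null(classifier)) {
      f <- file.path(dir, "detector.rds")
      if (!file.exists(f))
        stop("stage `detect` needs a model: run `train-detector` first")
      classifier <- readRDS(f)
    }
    logmsg("detect: detector=", cfg$detector,
        " step=5 p_min=0.30 cluster_cutoff=15")
    patterns <- cohort_patterns(get_cohort(), detector = cfg$detector,
                                classifier = classifier)
    write_patterns(patterns, file.path(dir, "patterns.csv"))
    out$patterns <- patterns
  }

  if (any(c("enroll", "identify", "evaluate") %in% stages) &&
      identical(cfg$matcher, "hog")) {
    logmsg("identify: matcher=hog sizeN=64 offsets=10 cell=2")
    hg <- run_hog_experiment(get_cohort())
    res <- hg$results; rep <- hg$report
    if ("identify" %in% stages)
      write.csv(res, file.path(dir, "results.csv"), row.names = FALSE)
    if ("evaluate" %in% stages) {
      jsonlite::write_json(list(overall = rep$overall, table = rep$table),
                           file.path(dir, "report.json"), auto_unbox = TRUE,
                           digits = NA)
      logmsg("evaluate: overall accuracy ", rep$overall, "%")
    }
    out$results <- res
    out$report <- rep
  } else if (any(c("enroll", "identify", "evaluate") %in% stages)) {
    if (is.null(patterns)) {
      f <- file.path(dir, "patterns.csv")
      if (!file.exists(f))
        stop("stage `enroll` needs patterns: run `detect` first")
      patterns <- read_patterns(f)
    }
    if (cfg$n_sessions == 1) {
      logmsg("identify: short-term, max_shift=30 step=5 trim=3/4")
      st <- run_short_term(patterns,
                           match_config(max_shift = cfg$max_shift %||% 30))
      if ("enroll" %in% stages)
        write_gallery(lapply(st$gallery, `[[`, 1), file.path(dir, "gallery.json"))
      res <- st$results; rep <- st$report
    } else {
      logmsg("identify: long-term, max_shift=50 step=5 trim=3/4 accept<20px")
      lt <- run_long_term(patterns,
                          match_config(max_shift = cfg$max_shift %||% 50))
      if ("enroll" %in% stages)
        for (s in names(lt$representatives))
          write_gallery(lt$representatives[[s]],
                        file.path(dir, paste0("gallery_", s, ".json")))
      res <- lt$results; rep <- lt$report
    }
    if ("identify" %in% stages)
      write.csv(res, file.path(dir, "results.csv"), row.names = FALSE)
    if ("evaluate" %in% stages) {
      jsonlite::write_json(list(overall = rep$overall, table = rep$table),
                           file.path(dir, "report.json"), auto_unbox = TRUE,
                           digits = NA)
      logmsg("evaluate: overall accuracy ", rep$overall, "%")
    }
    out$results <- res
    out$report <- rep
  }
  invisible(out)
}
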