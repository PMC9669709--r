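## Readers and writers for the plain-text interchange formats: TPS landmark
## files, long-format landmark CSV, ratings CSV, and JSON serialization of
## face spaces and fitted GPOR models.

#' Read landmark configurations from a TPS file
#'
#' Supports the common `LM=<k>` records followed by `k` whitespace-separated
#' coordinate lines, with optional `ID=`, `IMAGE=` and `SCALE=` lines
#' (`SCALE` is applied multiplicatively when present).
#'
#' @param path file path.
#' @return a named list of K x 2 matrices.
#' @export
read_tps <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  out <- list(); ids <- character()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^LM\\s*=", lines[i], ignore.case = TRUE)) {
      stop("malformed TPS file: expected LM= record at line ", i)
    }
    k <- as.integer(sub("^LM\\s*=\\s*", "", lines[i], ignore.case = TRUE))
    coords <- matrix(NA_real_, k, 2)
    for (j in seq_len(k)) {
      xy <- as.numeric(strsplit(lines[i + j], "\\s+")[[1]])
      if (length(xy) != 2 || anyNA(xy)) {
        stop("malformed coordinate line ", i + j)
      }
      coords[j, ] <- xy
    }
    i <- i + k + 1L
    id <- NA_character_; scale <- NA_real_
    while (i <= length(lines) && !grepl("^LM\\s*=", lines[i], ignore.case = TRUE)) {
      if (grepl("^ID\\s*=", lines[i], ignore.case = TRUE)) {
        id <- sub("^ID\\s*=\\s*", "", lines[i], ignore.case = TRUE)
      } else if (grepl("^SCALE\\s*=", lines[i], ignore.case = TRUE)) {
        scale <- as.numeric(sub("^SCALE\\s*=\\s*", "", lines[i],
                                ignore.case = TRUE))
      }
      i <- i + 1L
    }
    if (is.finite(scale)) coords <- coords * scale
    out[[length(out) + 1L]] <- coords
    ids <- c(ids, if (is.na(id)) as.character(length(out)) else id)
  }
  names(out) <- ids
  out
}

#' Write landmark configurations to a TPS file
#'
#' @param configs named list of K x 2 matrices.
#' @param path output path.
#' @export
write_tps <- function(configs, path) {
  ids <- names(configs) %||% as.character(seq_along(configs))
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(configs)) {
    m <- as_landmarks(configs[[i]])
    writeLines(c(paste0("LM=", nrow(m)),
                 paste(format(m[, 1], trim = TRUE), format(m[, 2], trim = TRUE)),
                 paste0("ID=", ids[i])), con)
  }
  invisible(path)
}

#' Read landmarks from long-format CSV
#'
#' Columns `face_id, landmark_id, x, y`; landmark order follows
#' `landmark_id`.
#'
#' @param path file path.
#' @return a named list of K x 2 matrices.
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("face_id", "landmark_id", "x", "y")
  if (!all(need %in% names(df))) {
    stop("landmark CSV must have columns: ", paste(need, collapse = ", "))
  }
  split_df <- split(df, df$face_id)
  lapply(split_df, function(d) {
    d <- d[order(d$landmark_id), ]
    as.matrix(d[, c("x", "y")])
  })
}

#' Write landmarks to long-format CSV
#'
#' @param configs named list of K x 2 matrices.
#' @param path output path.
#' @export
write_landmarks_csv <- function(configs, path) {
  ids <- names(configs) %||% as.character(seq_along(configs))
  rows <- do.call(rbind, lapply(seq_along(configs), function(i) {
    m <- as_landmarks(configs[[i]])
    data.frame(face_id = ids[i], landmark_id = seq_len(nrow(m)),
               x = m[, 1], y = m[, 2])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a face space to JSON
#'
#' @param space a [fit_face_space()] object.
#' @param path output path.
#' @export
write_face_space <- function(space, path) {
  jsonlite::write_json(list(
    n_landmarks = space$n_landmarks,
    mean_shape = space$mean_shape,
    loadings = space$loadings,
    pc_sd = space$pc_sd,
    explained_ratio = space$explained_ratio
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a face space from JSON
#'
#' @param path file path.
#' @return a `face_space` object.
#' @export
read_face_space <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean_shape = matrix(unlist(j$mean_shape), ncol = 2),
                 loadings = matrix(unlist(j$loadings),
                                   ncol = length(j$pc_sd)),
                 pc_sd = as.numeric(j$pc_sd),
                 explained_ratio = as.numeric(j$explained_ratio),
                 n_landmarks = as.integer(j$n_landmarks)),
            class = "face_space")
}

#' Read ordinal rating records from CSV
#'
#' Columns: `participant_id, trial, pc1..pcD, rating`.
#'
#' @param path file path.
#' @param R number of ordinal categories.
#' @return a named list of [ordinal_data()] objects, one per participant.
#' @export
read_ratings_csv <- function(path, R = 5L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  pc_cols <- grep("^pc[0-9]+$", names(df), value = TRUE)
  if (!length(pc_cols) || !all(c("participant_id", "rating") %in% names(df))) {
    stop("ratings CSV must have participant_id, pc1..pcD and rating columns")
  }
  pc_cols <- pc_cols[order(as.integer(sub("^pc", "", pc_cols)))]
  lapply(split(df, df$participant_id), function(d) {
    if ("trial" %in% names(d)) d <- d[order(d$trial), ]
    ordinal_data(as.matrix(d[, pc_cols, drop = FALSE]), d$rating, R)
  })
}

#' Write ordinal rating datasets to CSV
#'
#' @param datasets named list of [ordinal_data()] objects.
#' @param path output path.
#' @export
write_ratings_csv <- function(datasets, path) {
  ids <- names(datasets) %||% sprintf("s%02d", seq_along(datasets))
  rows <- do.call(rbind, lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    xm <- d$x
    colnames(xm) <- paste0("pc", seq_len(ncol(xm)))
    cbind(data.frame(participant_id = ids[i], trial = seq_len(d$N)),
          as.data.frame(xm), data.frame(rating = d$y))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted GPOR model to JSON
#'
#' Stores the hyperparameters, training inputs and MAP solution; the model
#' can be reconstructed exactly with [read_gpor_model()].
#'
#' @param model a [fit_gpor()] model.
#' @param path output path.
#' @export
write_gpor_model <- function(model, path) {
  jsonlite::write_json(list(
    eta = model$hyper$eta, sigma = model$hyper$sigma, b = model$hyper$b,
    R = model$data$R, x = model$data$x, y = model$data$y,
    f_map = model$f_map, log_evidence = model$log_evidence
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Reconstruct a GPOR model from JSON
#'
#' Re-runs the (deterministic) MAP computation on the stored data and
#' hyperparameters.
#'
#' @param path file path.
#' @return a `gpor_model`.
#' @export
read_gpor_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  x <- j$x
  if (is.null(dim(x))) x <- matrix(unlist(x), ncol = length(j$eta))
  data <- ordinal_data(as.matrix(x), j$y, as.integer(j$R))
  hyper <- gpor_hyper(j$eta, j$sigma, j$b)
  fit_gpor(data, hyper)
}
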