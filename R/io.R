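#' Write a synthetic dataset to HDF5
#'
#' Layout: `/participants/p<id>/<condition>/trial_<k>/{position, velocity,
#' eeg}` with per-trial metadata (choice, rt, amplitude, accuracy) stored
#' as HDF5 attributes of the trial group, channel labels as a string array
#' at `/channels`, and the generator seed as a file-level attribute.
#'
#' @param dataset An `actsense_dataset` from [generate_dataset()].
#' @param path Output `.h5` path (overwritten).
#' @return `path`, invisibly.
#' @export
write_dataset_h5 <- function(dataset, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "participants")
  rhdf5::h5write(attr(dataset$trials[[1]]$eeg, "labels") %||%
                   paste0("ch", seq_len(ncol(dataset$trials[[1]]$eeg))),
                 path, "channels")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(dataset$cfg$seed, fid, "seed")
  rhdf5::H5Fclose(fid)
  done <- character(0)
  for (tr in dataset$trials) {
    pgrp <- paste0("participants/p", tr$participant)
    cgrp <- paste0(pgrp, "/", tr$condition)
    tgrp <- paste0(cgrp, "/trial_", tr$trial)
    for (g in c(pgrp, cgrp, tgrp)) {
      if (!g %in% done) {
        rhdf5::h5createGroup(path, g)
        done <- c(done, g)
      }
    }
    rhdf5::h5write(tr$position$x, path, paste0(tgrp, "/position"))
    rhdf5::h5write(tr$velocity, path, paste0(tgrp, "/velocity"))
    rhdf5::h5write(unclass(tr$eeg), path, paste0(tgrp, "/eeg"))
    fid <- rhdf5::H5Fopen(path)
    gid <- rhdf5::H5Gopen(fid, tgrp)
    rhdf5::h5writeAttribute(tr$choice, gid, "choice")
    rhdf5::h5writeAttribute(tr$rt, gid, "rt")
    rhdf5::h5writeAttribute(tr$amplitude, gid, "amplitude")
    rhdf5::h5writeAttribute(tr$accuracy, gid, "accuracy")
    rhdf5::H5Gclose(gid)
    rhdf5::H5Fclose(fid)
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a synthetic dataset from HDF5
#'
#' @param path Path written by [write_dataset_h5()].
#' @param fs Sampling rate to attach to traces.
#' @return List of trial records.
#' @export
read_dataset_h5 <- function(path, fs) {
  labels <- as.character(rhdf5::h5read(path, "channels"))
  idx <- rhdf5::h5ls(path)
  tgroups <- idx$group[idx$name == "eeg"]
  trials <- lapply(tgroups, function(g) {
    parts <- strsplit(sub("^/", "", g), "/")[[1]]
    eeg <- rhdf5::h5read(path, paste0(g, "/eeg"))
    fid <- rhdf5::H5Fopen(path)
    gid <- rhdf5::H5Gopen(fid, g)
    at <- rhdf5::h5readAttributes(fid, g)
    meta <- list(choice = as.vector(at$choice), rt = as.vector(at$rt),
                 amplitude = as.vector(at$amplitude),
                 accuracy = as.vector(at$accuracy))
    rhdf5::H5Gclose(gid); rhdf5::H5Fclose(fid)
    list(participant = as.integer(sub("^p", "", parts[2])),
         condition = parts[3],
         trial = as.integer(sub("^trial_", "", parts[4])),
         position = position_trace(
           as.numeric(rhdf5::h5read(path, paste0(g, "/position"))), fs = fs),
         velocity = as.numeric(rhdf5::h5read(path, paste0(g, "/velocity"))),
         eeg = structure(as.matrix(eeg), labels = labels, fs = fs),
         choice = meta$choice, rt = meta$rt, amplitude = meta$amplitude,
         accuracy = meta$accuracy)
  })
  rhdf5::h5closeAll()
  trials
}

#' Serialise decoder / forward models to HDF5
#'
#' Layout `/models/<participant>/<condition>/{g, f, lambda, lags,
#' channels}`.
#'
#' @param models Nested list `models[[participant]][[condition]]`, each
#'   with `decoder` (a `decoder_model`) and `forward` (a `forward_model`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_models_h5 <- function(models, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "models")
  for (pn in names(models)) {
    rhdf5::h5createGroup(path, paste0("models/", pn))
    for (cn in names(models[[pn]])) {
      g <- paste0("models/", pn, "/", cn)
      rhdf5::h5createGroup(path, g)
      m <- models[[pn]][[cn]]
      rhdf5::h5write(m$decoder$g, path, paste0(g, "/g"))
      rhdf5::h5write(unclass(m$forward), path, paste0(g, "/f"))
      rhdf5::h5write(m$decoder$lambda, path, paste0(g, "/lambda"))
      rhdf5::h5write(m$decoder$lag_spec$lags, path, paste0(g, "/lags"))
      rhdf5::h5write(m$decoder$labels, path, paste0(g, "/channels"))
    }
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Serialise posterior draws to HDF5
#'
#' Layout `/posterior/<parameter>/chain_<c>`.
#'
#' @param samples A `ddm_posterior`.
#' @param path Output path.
#' @param params Parameters to store (default group-level + deviance).
#' @return `path`, invisibly.
#' @export
write_posterior_h5 <- function(samples, path,
                               params = c(samples$group_params, "deviance")) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "posterior")
  for (pn in params) {
    g <- paste0("posterior/", pn)
    rhdf5::h5createGroup(path, g)
    for (c in seq_along(samples$chains)) {
      rhdf5::h5write(samples$chains[[c]][, pn], path,
                     paste0(g, "/chain_", c))
    }
  }
  rhdf5::h5closeAll()
  invisible(path)
}
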