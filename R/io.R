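# On-disk dataset container: one directory with meta.json plus, per subject,
# a little-endian float32 binary of the trials in C order (trial, channel,
# sample) and a labels.csv (trial_index, target, role).

#' Write and read a multi-subject dataset directory
#'
#' The container is plain files: `meta.json` holds the sampling rate, the
#' codebook, the subject list and the generation config/seed; each subject has
#' `<id>_trials.bin` (little-endian float32, C order `trials x channels x
#' samples`) and `<id>_labels.csv` with columns `trial_index`, `target`,
#' `role`. Values are stored in single precision; a read followed by a write
#' reproduces the files byte for byte.
#'
#' @param ds A `cvep_dataset`.
#' @param dir Directory to create/read.
#' @return `write_cvep_dataset()` returns `dir` invisibly;
#'   `read_cvep_dataset()` returns a `cvep_dataset` (without generator
#'   models, which are not serialized).
#' @export
write_cvep_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "cvep_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(ds$subjects, function(s) s$subject_id, character(1))
  meta <- list(
    fs = ds$subjects[[1]]$fs,
    codebook = list(
      bits = paste(ds$codebook$base$bits, collapse = ""),
      bit_rate = ds$codebook$bit_rate,
      n_targets = ds$codebook$n_targets,
      lag_bits = ds$codebook$lag_bits,
      reference_target = ds$codebook$reference_target
    ),
    subjects = as.list(ids),
    dims = lapply(ds$subjects, function(s) as.list(dim(s$trials))),
    seed = ds$seed,
    config = ds$config[setdiff(names(ds$config), "clusters")]
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (s in ds$subjects) {
    # C order trials x channels x samples == R array [samples, channels, trials]
    con <- file(file.path(dir, paste0(s$subject_id, "_trials.bin")), "wb")
    writeBin(as.numeric(aperm(s$trials, c(2, 1, 3))), con,
             size = 4, endian = "little")
    close(con)
    utils::write.csv(
      data.frame(trial_index = seq_along(s$labels), target = s$labels,
                 role = s$role),
      file.path(dir, paste0(s$subject_id, "_labels.csv")), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cvep_dataset
#' @export
read_cvep_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  cbm <- meta$codebook
  cb <- codebook(as_code(as.integer(strsplit(cbm$bits, "")[[1]]), cbm$bit_rate),
                 n_targets = cbm$n_targets, lag_bits = cbm$lag_bits,
                 bit_rate = cbm$bit_rate, reference_target = cbm$reference_target)
  subjects <- lapply(seq_along(meta$subjects), function(i) {
    id <- meta$subjects[[i]]
    # dims may simplify to a matrix (rows = subjects) or stay a list
    d <- if (is.matrix(meta$dims)) {
      as.integer(meta$dims[i, ])
    } else {
      as.integer(unlist(meta$dims[[i]]))
    }  # [Nc, Nt, n]
    con <- file(file.path(dir, paste0(id, "_trials.bin")), "rb")
    raw <- readBin(con, "numeric", n = prod(d), size = 4, endian = "little")
    close(con)
    trials <- aperm(array(raw, dim = d[c(2, 1, 3)]), c(2, 1, 3))
    lab <- utils::read.csv(file.path(dir, paste0(id, "_labels.csv")))
    structure(
      list(subject_id = id, trials = trials, labels = as.integer(lab$target),
           role = as.character(lab$role), fs = meta$fs, codebook = cb,
           model = NULL),
      class = "cvep_subject"
    )
  })
  structure(
    list(subjects = subjects, codebook = cb, config = as.list(meta$config),
         seed = meta$seed),
    class = "cvep_dataset"
  )
}
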