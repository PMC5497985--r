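#' Write an epoch set to a self-describing text container
#'
#' The container is a directory holding a JSON sidecar (`meta.json`: subject,
#' condition, sampling rate, channel names, full time axis, CS time, trial
#' count, format version) and one CSV per trial (`trial_001.csv`, ...;
#' columns = channels, rows = samples) with voltages printed at full double
#' precision (`%.17g`), so a write/read round trip is bit-exact.
#'
#' @param epochs An [epoch_set()].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(format = "teplab-epochs", version = 1L,
               subject_id = epochs$subject_id, condition = epochs$condition,
               sampling_rate = epochs$sampling_rate,
               cs_time_ms = epochs$cs_time_ms,
               channel_names = epochs$channel_names,
               time_ms = epochs$time_ms,
               n_trials = dim(epochs$data)[3])
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (tr in seq_len(dim(epochs$data)[3])) {
    mat <- t(epochs$data[, , tr])                 # samples x channels
    lines <- c(paste(epochs$channel_names, collapse = ","),
               apply(mat, 1, function(r) paste(sprintf("%.17g", r),
                                               collapse = ",")))
    writeLines(lines, file.path(path, sprintf("trial_%03d.csv", tr)))
  }
  invisible(path)
}

#' Read an epoch set from its text container
#'
#' Inverse of [write_epochs()]. Malformed containers fail with an error
#' naming the offending field.
#'
#' @param path Container directory.
#' @return An [epoch_set()].
#' @export
read_epochs <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop("not an epoch container (no meta.json): ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("subject_id", "condition", "sampling_rate", "channel_names",
                  "time_ms", "n_trials")) {
    if (is.null(meta[[field]])) {
      stop("malformed epoch container: missing field '", field, "' in ", meta_path)
    }
  }
  n_tr <- meta$n_trials
  files <- file.path(path, sprintf("trial_%03d.csv", seq_len(n_tr)))
  miss <- files[!file.exists(files)]
  if (length(miss)) stop("epoch container missing trial files: ", miss[1])
  dat <- array(NA_real_, dim = c(length(meta$channel_names),
                                 length(meta$time_ms), n_tr))
  for (tr in seq_len(n_tr)) {
    m <- utils::read.csv(files[tr], check.names = FALSE)
    if (!identical(names(m), as.character(meta$channel_names))) {
      stop("malformed epoch container: channel_names mismatch in ", files[tr])
    }
    dat[, , tr] <- t(as.matrix(m))
  }
  cs <- meta$cs_time_ms
  if (is.null(cs)) cs <- NA_real_
  epoch_set(dat, meta$time_ms, meta$channel_names, meta$sampling_rate,
            meta$condition, meta$subject_id, cs_time_ms = cs)
}

# Stable fingerprint of a configuration, embedded in manifests so artifacts
# record exactly which settings produced them.
config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

spec_to_list <- function(spec) {
  list(seed = spec$seed, tasks = spec$tasks,
       protocol = unclass(spec$protocol),
       correlation_targets = spec$correlation_targets,
       groups = spec$groups)
}

#' Write a cohort dataset to a directory
#'
#' Layout: `manifest.json` (seed, config hash, group sizes, protocol),
#' `subjects.csv` (ground truth, per-subject seeds, questionnaire scores),
#' `logs/<subject>_<task>.csv` per behavioral task, and — when
#' `epochs = TRUE` — `epochs/<subject>/{single,paired}/` text containers
#' ([write_epochs()]). Epochs are regenerated from the per-subject seeds, so
#' writing them is deterministic but costs the bulk of the run time.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory.
#' @param epochs Also materialise per-subject epoch containers?
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, epochs = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec_list <- spec_to_list(cohort$spec)
  manifest <- list(format = "teplab-cohort", version = 1L,
                   seed = cohort$spec$seed,
                   config_hash = config_hash(spec_list),
                   n_subjects = nrow(cohort$subjects),
                   groups = lapply(cohort$spec$groups,
                                   function(g) list(label = g$label, n = g$n)),
                   spec = spec_list,
                   epochs_written = epochs)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_table_csv(cohort$subjects, file.path(dir, "subjects.csv"))
  if (!is.null(cohort$logs)) {
    dir.create(file.path(dir, "logs"), showWarnings = FALSE)
    for (id in names(cohort$logs)) {
      for (task in names(cohort$logs[[id]])) {
        write_table_csv(cohort$logs[[id]][[task]],
                        file.path(dir, "logs", paste0(id, "_", task, ".csv")))
      }
    }
  }
  if (epochs) {
    for (id in cohort$subjects$subject_id) {
      ep <- subject_epochs(cohort, id)
      write_epochs(ep$single, file.path(dir, "epochs", id, "single"))
      write_epochs(ep$paired, file.path(dir, "epochs", id, "paired"))
    }
  }
  invisible(dir)
}

#' Read a cohort dataset directory
#'
#' Reconstructs the subjects table and behavioral logs written by
#' [write_cohort()]. Epoch containers are listed but not loaded; use
#' [read_epochs()] on `epochs/<subject>/<condition>` as needed.
#'
#' @param dir Cohort directory.
#' @return List: `manifest`, `subjects`, `logs` (or `NULL`), `epoch_dirs`.
#' @export
read_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop("not a cohort directory (no manifest.json): ", dir)
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"),
                              stringsAsFactors = FALSE)
  logs <- NULL
  log_dir <- file.path(dir, "logs")
  if (dir.exists(log_dir)) {
    logs <- lapply(subjects$subject_id, function(id) {
      tasks <- c("stop", "choice", "arithmetic", "memory")
      out <- lapply(tasks, function(task) {
        f <- file.path(log_dir, paste0(id, "_", task, ".csv"))
        if (file.exists(f)) utils::read.csv(f, stringsAsFactors = FALSE) else NULL
      })
      names(out) <- tasks
      out
    })
    names(logs) <- subjects$subject_id
  }
  ep_root <- file.path(dir, "epochs")
  epoch_dirs <- if (dir.exists(ep_root)) list.dirs(ep_root, recursive = FALSE)
                else character()
  list(manifest = manifest, subjects = subjects, logs = logs,
       epoch_dirs = epoch_dirs)
}

# CSV writer with deterministic full-precision formatting (doubles printed
# %.17g), so identical tables give byte-identical files.
write_table_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- "NA"
      out[[j]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}
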