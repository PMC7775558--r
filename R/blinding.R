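# Blinded randomization of image/annotation filenames across pooled
# conditions, with a persisted key for later unblinding.
#
# Files from all conditions of one experiment are pooled and copied under
# randomized zero-padded numbers so the annotator cannot tell conditions
# apart (nor drift between batches); the id -> original-name key is written
# alongside as JSON and must be kept until analysis is complete. Originals
# are never modified: everything is copy semantics.

pad_ids <- function(n) sprintf("%0*d", max(3L, nchar(n)), seq_len(n))

# run expr under a seeded RNG without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build a blinding key for a set of files
#'
#' Draws the seeded random permutation assigning contiguous zero-padded ids
#' 1..N to the original filenames. This is the pure core of
#' [randomize_images()]: no files are touched, so permutation behaviour
#' (determinism, uniformity) can be audited directly.
#'
#' @param files Character vector of >= 2 file paths or names.
#' @param seed Integer seed; `NULL` draws one from OS entropy and records it.
#' @return A `blinding_key`: list with `entries` (named character vector,
#'   id -> original basename), `seed`, `created`.
#' @export
randomization_key <- function(files, seed = NULL) {
  if (length(files) < 2L) stop("need at least 2 files to blind", call. = FALSE)
  base <- basename(files)
  if (anyDuplicated(base)) {
    stop("duplicate basenames would make the key ambiguous: ",
         paste(unique(base[duplicated(base)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(seed)) {
    seed <- tryCatch({
      b <- readBin("/dev/urandom", "integer", n = 1L)
      abs(b) %% .Machine$integer.max
    }, error = function(e) {
      as.integer(as.numeric(Sys.time()) * 1000) %% .Machine$integer.max
    })
  }
  seed <- as.integer(seed)
  n <- length(files)
  perm <- with_seed(seed, sample.int(n))
  entries <- base[perm]
  names(entries) <- pad_ids(n)
  structure(list(entries = entries, seed = seed,
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "blinding_key")
}

#' @export
print.blinding_key <- function(x, ...) {
  cat(sprintf("blinding key: %d files, seed %d, created %s\n",
              length(x$entries), x$seed, x$created))
  invisible(x)
}

#' Write / read a blinding key as JSON
#'
#' The key is persisted as JSON with an explicit seed so the blinding is
#' auditable and reproducible.
#'
#' @param key A `blinding_key`.
#' @param path JSON file path.
#' @return `path` (write) or a `blinding_key` (read).
#' @export
write_blinding_key <- function(key, path) {
  stopifnot(inherits(key, "blinding_key"))
  jsonlite::write_json(
    list(entries = as.list(key$entries), seed = key$seed,
         created = key$created),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_blinding_key
#' @export
read_blinding_key <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(entries = unlist(obj$entries), seed = as.integer(obj$seed),
                 created = obj$created),
            class = "blinding_key")
}

#' Randomize files into a blinded folder
#'
#' Copies the input files into `out_dir/randomized/`, each named by its
#' randomized id with the original extension, and writes the key as
#' `key.json` alongside. Originals are left untouched. The permutation is
#' fully determined by the seed.
#'
#' @param files Character vector of >= 2 existing files.
#' @param out_dir Directory under which `randomized/` is created.
#' @param seed Integer seed; `NULL` draws one from OS entropy.
#' @param force Proceed even if `out_dir/randomized/` exists and is
#'   non-empty.
#' @return The `blinding_key`, invisibly.
#' @export
randomize_images <- function(files, out_dir, seed = NULL, force = FALSE) {
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop("input files not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rand_dir <- file.path(out_dir, "randomized")
  if (dir.exists(rand_dir) && length(dir(rand_dir)) > 0L && !force) {
    stop("'", rand_dir, "' already exists and is non-empty; ",
         "use force = TRUE to overwrite", call. = FALSE)
  }
  key <- randomization_key(files, seed)
  dir.create(rand_dir, recursive = TRUE, showWarnings = FALSE)
  src <- files[match(key$entries, basename(files))]
  ext <- tools::file_ext(key$entries)
  dest <- file.path(rand_dir, paste0(names(key$entries),
                                     ifelse(nzchar(ext), paste0(".", ext), "")))
  ok <- file.copy(src, dest, overwrite = force)
  if (!all(ok)) stop("failed to copy: ", paste(src[!ok], collapse = ", "),
                     call. = FALSE)
  write_blinding_key(key, file.path(rand_dir, "key.json"))
  invisible(key)
}

#' Unblind result files using a key
#'
#' Copies (never moves) result files into `out_dir/unblinded/`, renamed after
#' the original image stems recorded in the key. Each result file's stem must
#' be a randomized id present in the key; unknown stems are reported together
#' as orphans.
#'
#' @param key A `blinding_key` or path to a `key.json`.
#' @param result_files Files named by randomized id (e.g. `0007.txt`).
#' @param out_dir Directory under which `unblinded/` is created.
#' @return Character vector of the unblinded file paths.
#' @export
unblind_files <- function(key, result_files, out_dir) {
  if (is.character(key) && length(key) == 1L) key <- read_blinding_key(key)
  stopifnot(inherits(key, "blinding_key"))
  stems <- tools::file_path_sans_ext(basename(result_files))
  known <- stems %in% names(key$entries)
  if (!all(known)) {
    stop("result files not present in the key (orphans): ",
         paste(basename(result_files)[!known], collapse = ", "),
         call. = FALSE)
  }
  originals <- key$entries[stems]
  if (anyNA(originals) || any(!nzchar(originals))) {
    bad <- stems[is.na(originals) | !nzchar(originals)]
    stop("key entry missing for id(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ext <- tools::file_ext(basename(result_files))
  dest_names <- paste0(tools::file_path_sans_ext(originals),
                       ifelse(nzchar(ext), paste0(".", ext), ""))
  if (anyDuplicated(dest_names)) {
    stop("renaming collision after unblinding: ",
         paste(unique(dest_names[duplicated(dest_names)]), collapse = ", "),
         call. = FALSE)
  }
  ub_dir <- file.path(out_dir, "unblinded")
  dir.create(ub_dir, recursive = TRUE, showWarnings = FALSE)
  dest <- file.path(ub_dir, dest_names)
  ok <- file.copy(result_files, dest, overwrite = TRUE)
  if (!all(ok)) stop("failed to copy: ",
                     paste(result_files[!ok], collapse = ", "), call. = FALSE)
  dest
}
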