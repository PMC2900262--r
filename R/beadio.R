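# Readers/writers for the pipeline's tabular artifacts.  One dialect
# throughout: CSV (comma, '.' decimal, mandatory header) for instrument-like
# event tables and Ct tables; TSV for layouts, probe tables and results.

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(what, ": missing column(s) ", paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' Read a bead-event table
#'
#' CSV with header `well,region,event,fluorescence`: one row per flow event
#' of one bead region in one well.  Rejects negative fluorescence, malformed
#' well coordinates and duplicate (well, region, event) triples, reporting
#' the offending file line.
#'
#' @param path CSV file path.
#' @return A validated data.frame (well, region, event, fluorescence).
#' @export
read_bead_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("well", "region", "event", "fluorescence"),
                  "bead-event table")
  line <- function(i) i + 1L  # header occupies line 1
  bad <- which(!is_valid_well(df$well))
  if (length(bad) > 0) {
    stop("malformed well '", df$well[bad[1]], "' at line ", line(bad[1]))
  }
  bad <- which(!is.finite(df$fluorescence) | df$fluorescence < 0)
  if (length(bad) > 0) {
    stop("negative or non-numeric fluorescence at line ", line(bad[1]))
  }
  key <- paste(df$well, df$region, df$event, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("duplicate (well, region, event) at line ", line(dup[1]))
  }
  df$region <- as.integer(df$region)
  df$event <- as.integer(df$event)
  df
}

#' Write a bead-event table
#'
#' @param events Data.frame with columns well, region, event, fluorescence
#'   (extra columns are dropped).
#' @param path Output CSV path.
#' @export
write_bead_events <- function(events, path) {
  require_columns(events, c("well", "region", "event", "fluorescence"),
                  "bead-event table")
  utils::write.csv(events[, c("well", "region", "event", "fluorescence")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plate layout
#'
#' TSV with header `well sample_id role replicate_index`.  Roles are `test`,
#' `reference` or `background`; wells must be unique A1-H12 coordinates.
#' A layout without background wells is accepted here (quantification
#' rejects it when a background model is required).
#'
#' @param path TSV file path.
#' @return A validated layout data.frame.
#' @export
read_plate_layout <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("well", "sample_id", "role", "replicate_index"),
                  "plate layout")
  bad <- which(!is_valid_well(df$well))
  if (length(bad) > 0) {
    stop("malformed well '", df$well[bad[1]], "' at line ", bad[1] + 1L)
  }
  if (anyDuplicated(df$well)) {
    stop("duplicate well '", df$well[which(duplicated(df$well))[1]],
         "' in layout")
  }
  bad <- which(!df$role %in% c("test", "reference", "background"))
  if (length(bad) > 0) {
    stop("unknown role '", df$role[bad[1]], "' at line ", bad[1] + 1L)
  }
  if (any(df$replicate_index < 1)) stop("replicate_index must be >= 1")
  df$replicate_index <- as.integer(df$replicate_index)
  df
}

#' Write a plate layout
#' @param layout Layout data.frame (extra columns are dropped).
#' @param path Output TSV path.
#' @export
write_plate_layout <- function(layout, path) {
  require_columns(layout, c("well", "sample_id", "role", "replicate_index"),
                  "plate layout")
  utils::write.table(
    layout[, c("well", "sample_id", "role", "replicate_index")],
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a capture-probe table
#'
#' TSV with header `id sequence length_nt parent_id mismatch_count
#' bead_region` (sequences uppercase DNA; `parent_id`/`bead_region` may be
#' empty).  Validates sequence alphabet, the length column against the
#' actual sequence length, probe-id uniqueness, and the convention that a
#' probe has `mismatch_count = 0` exactly when it has no (distinct) parent.
#'
#' @param path TSV file path.
#' @return A data.frame of probe records.
#' @export
read_probe_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = NULL)
  require_columns(df, c("id", "sequence", "length_nt", "parent_id",
                        "mismatch_count", "bead_region"), "probe table")
  if (anyDuplicated(df$id)) {
    stop("duplicate probe_id '", df$id[which(duplicated(df$id))[1]], "'")
  }
  for (i in seq_len(nrow(df))) {
    df$sequence[i] <- normalize_dna(df$sequence[i])
    if (nchar(df$sequence[i]) != df$length_nt[i]) {
      stop("probe ", df$id[i], ": length_nt (", df$length_nt[i],
           ") does not match sequence length (", nchar(df$sequence[i]), ")")
    }
    if (nchar(df$sequence[i]) < 18 || nchar(df$sequence[i]) > 30) {
      stop("probe ", df$id[i], ": sequence length outside [18, 30]")
    }
    no_parent <- is.na(df$parent_id[i]) || df$parent_id[i] == "" ||
      df$parent_id[i] == df$id[i]
    if ((df$mismatch_count[i] == 0) != no_parent) {
      stop("probe ", df$id[i],
           ": mismatch_count must be 0 iff parent_id is empty or self")
    }
  }
  df$length_nt <- as.integer(df$length_nt)
  df$mismatch_count <- as.integer(df$mismatch_count)
  df$bead_region <- suppressWarnings(as.integer(df$bead_region))
  df
}

#' Read a qPCR Ct table
#'
#' CSV with header `sample,assay,replicate,ct`.  Ct values must lie in the
#' open interval (0, 45) cycles.
#'
#' @param path CSV file path.
#' @return A validated data.frame.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("sample", "assay", "replicate", "ct"), "Ct table")
  bad <- which(!is.finite(df$ct) | df$ct <= 0 | df$ct >= 45)
  if (length(bad) > 0) {
    stop("Ct value ", df$ct[bad[1]], " outside (0, 45) at line ",
         bad[1] + 1L)
  }
  df$replicate <- as.integer(df$replicate)
  df
}

#' Write a Ct table
#' @param ct Ct data.frame (sample, assay, replicate, ct).
#' @param path Output CSV path.
#' @export
write_ct_table <- function(ct, path) {
  require_columns(ct, c("sample", "assay", "replicate", "ct"), "Ct table")
  utils::write.csv(ct[, c("sample", "assay", "replicate", "ct")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a results table
#'
#' TSV, fixed column order as given, numeric columns rounded to 6
#' significant digits.
#'
#' @param table Any data.frame of results.
#' @param path Output TSV path.
#' @export
write_results <- function(table, path) {
  out <- table
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- run configuration as flat key = value text -----------------------------

#' Write an assay configuration as key = value text
#'
#' Scalar fields are written one per line; named efficiency maps use dotted
#' keys (`eff_1mm.miR-27a = 0.7`); integer vectors are comma-separated.
#'
#' @param config An [assay_config()].
#' @param path Output file path.
#' @export
write_assay_config <- function(config, path) {
  stopifnot(inherits(config, "assay_config"))
  lines <- character(0)
  for (key in names(config)) {
    val <- config[[key]]
    if (!is.null(names(val))) {
      lines <- c(lines, sprintf("%s.%s = %s", key, names(val),
                                format(unname(val), digits = 15)))
    } else if (length(val) > 1) {
      lines <- c(lines, sprintf("%s = %s", key,
                                paste(format(val, digits = 15),
                                      collapse = ",")))
    } else {
      lines <- c(lines, sprintf("%s = %s", key, format(val, digits = 15)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an assay configuration from key = value text
#'
#' Unknown keys are errors (typo protection).
#'
#' @param path File written by [write_assay_config()].
#' @return An [assay_config()].
#' @export
read_assay_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  known <- names(formals(assay_config))
  args <- list()
  maps <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(m) != 3) stop("malformed config line: ", ln)
    key <- trimws(m[2]); val <- trimws(m[3])
    if (grepl(".", key, fixed = TRUE)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      base <- parts[1]; sub <- paste(parts[-1], collapse = ".")
      if (!base %in% known) stop("unknown config key: ", key)
      maps[[base]] <- c(maps[[base]],
                        stats::setNames(as.numeric(val), sub))
    } else {
      if (!key %in% known) stop("unknown config key: ", key)
      args[[key]] <- if (key == "signal_mode") val
        else if (grepl(",", val, fixed = TRUE))
          as.numeric(strsplit(val, ",")[[1]])
        else as.numeric(val)
    }
  }
  do.call(assay_config, c(args, maps))
}

#' Write a simulated plate to disk
#'
#' Emits the bead-event CSV, the plate-layout TSV, the (well, region) to
#' probe map TSV and the configuration, under a common file prefix.
#'
#' @param plate A `simulated_plate`.
#' @param prefix Path prefix; files `<prefix>_events.csv`,
#'   `<prefix>_layout.tsv`, `<prefix>_probes.tsv`, `<prefix>_config.txt`.
#' @return Named character vector of the paths written.
#' @export
write_plate <- function(plate, prefix) {
  stopifnot(inherits(plate, "simulated_plate"))
  paths <- c(events = paste0(prefix, "_events.csv"),
             layout = paste0(prefix, "_layout.tsv"),
             probes = paste0(prefix, "_probes.tsv"),
             config = paste0(prefix, "_config.txt"))
  write_bead_events(plate$events, paths["events"])
  write_plate_layout(plate$layout, paths["layout"])
  utils::write.table(plate$probe_map, paths["probes"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_assay_config(plate$config, paths["config"])
  invisible(paths)
}
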