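#' Construct a molecular structure
#'
#' A `Structure` is one molecular configuration: atomic numbers, Cartesian
#' coordinates in Angstrom, an identifier, the identifier of the parent
#' molecule (the unit of ranking, e.g. an InChIKey), and a named list of
#' scalar properties.
#'
#' @param structure_id character scalar identifying this configuration.
#' @param group_id character scalar identifying the parent molecule.
#' @param atomic_numbers integer vector of nuclear charges, all >= 1.
#' @param positions n x 3 numeric matrix of coordinates (Angstrom).
#' @param properties named list (or named numeric vector) of scalar
#'   properties, e.g. `list(energy = -1.2)`.
#' @return an object of class `Structure`.
#' @export
structure_new <- function(structure_id, group_id, atomic_numbers, positions,
                          properties = list()) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  atomic_numbers <- as.integer(atomic_numbers)
  properties <- as.list(properties)
  s <- structure(
    list(
      structure_id = as.character(structure_id),
      group_id = as.character(group_id),
      atomic_numbers = atomic_numbers,
      positions = positions,
      properties = properties
    ),
    class = "Structure"
  )
  validate_structure(s)
  s
}

#' Validate a Structure's invariants
#'
#' Checks that atom counts agree, nuclear charges are positive, coordinates
#' are finite, and no two atoms coincide.
#'
#' @param s a `Structure`.
#' @return `s`, invisibly, if valid; otherwise an error.
#' @export
validate_structure <- function(s) {
  n <- length(s$atomic_numbers)
  if (n < 1L) stop("structure '", s$structure_id, "': no atoms")
  if (!is.matrix(s$positions) || ncol(s$positions) != 3L ||
      nrow(s$positions) != n) {
    stop("structure '", s$structure_id,
         "': positions must be an n x 3 matrix matching atomic_numbers")
  }
  if (any(s$atomic_numbers < 1L)) {
    stop("structure '", s$structure_id, "': atomic numbers must be >= 1")
  }
  if (!all(is.finite(s$positions))) {
    stop("structure '", s$structure_id, "': non-finite coordinates")
  }
  if (n > 1L) {
    d <- stats::dist(s$positions)
    if (any(d <= 0)) {
      stop("structure '", s$structure_id, "': coincident atoms (zero distance)")
    }
  }
  invisible(s)
}

#' @export
print.Structure <- function(x, ...) {
  cat("<Structure ", x$structure_id, "> group=", x$group_id,
      " atoms=", length(x$atomic_numbers),
      " props={", paste(names(x$properties), collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' Construct a conformer group
#'
#' All configurations sharing one parent-molecule identifier; the unit of
#' ranking and of train/test splitting.
#'
#' @param group_id character scalar.
#' @param structures list of `Structure` objects, all with this `group_id`.
#' @return an object of class `ConformerGroup`.
#' @export
conformer_group <- function(group_id, structures) {
  gid <- vapply(structures, function(s) s$group_id, character(1))
  if (length(structures) && !all(gid == group_id)) {
    stop("all member structures must carry group_id '", group_id, "'")
  }
  structure(list(group_id = as.character(group_id), structures = structures),
            class = "ConformerGroup")
}

#' @export
length.ConformerGroup <- function(x) length(x$structures)

#' @export
print.ConformerGroup <- function(x, ...) {
  cat("<ConformerGroup ", x$group_id, "> n=", length(x$structures), "\n",
      sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Extended-XYZ I/O
#
# Frame layout:
#   line 1: atom count
#   line 2: whitespace-separated key=value metadata (group_id, structure_id,
#           one key per scalar property; values with spaces may be quoted)
#   lines 3..: symbol x y z
# Plain XYZ is the same without key=value metadata; group ids and properties
# then come from a sidecar table keyed by structure_id.
# ---------------------------------------------------------------------------

# Parse a key=value comment line into a named character vector.
.parse_kv <- function(line) {
  toks <- regmatches(
    line,
    gregexpr('[^\\s=]+="[^"]*"|[^\\s=]+=[^\\s]+', line, perl = TRUE)
  )[[1]]
  if (!length(toks)) return(character(0))
  keys <- sub("=.*$", "", toks)
  vals <- sub("^[^=]+=", "", toks)
  vals <- gsub('^"|"$', "", vals)
  names(vals) <- keys
  vals
}

.format_kv <- function(kv) {
  vals <- vapply(kv, function(v) {
    v <- as.character(v)
    if (grepl("\\s", v)) paste0('"', v, '"') else v
  }, character(1))
  paste(paste0(names(kv), "=", vals), collapse = " ")
}

#' Read structures from an (extended-)XYZ file
#'
#' For `format = "extxyz"` each frame's comment line holds
#' `key=value` metadata: `group_id`, optionally `structure_id`, and one key
#' per scalar property (numeric values).  For `format = "xyz"` metadata is
#' taken from `sidecar`, a delimited table with a header row containing at
#' least `structure_id` and `group_id` columns; remaining numeric columns
#' become properties.  Plain-XYZ frames are matched to sidecar rows by the
#' first token of the comment line if non-empty, else by frame number
#' (`frame_1`, `frame_2`, ...).
#'
#' @param path file path.
#' @param format `"extxyz"` (default) or `"xyz"`.
#' @param sidecar path to a delimited table (csv/tsv inferred from the
#'   separator on the header line) used when `format = "xyz"`.
#' @return list of `Structure` objects in file order.
#' @export
read_structures <- function(path, format = c("extxyz", "xyz"), sidecar = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  side <- NULL
  if (format == "xyz" && !is.null(sidecar)) {
    side <- read_property_table(sidecar)
  }
  out <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) {
      i <- i + 1L
      next
    }
    frame <- frame + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) {
      stop("frame ", frame, ": malformed atom-count line: '", lines[i], "'")
    }
    if (i + 1L + n > length(lines)) {
      stop("frame ", frame, ": truncated (expected ", n, " atom lines)")
    }
    comment <- lines[i + 1L]
    atom_lines <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(atom_lines), "\\s+")
    bad <- which(vapply(toks, length, integer(1)) < 4L)
    if (length(bad)) {
      stop("frame ", frame, ": malformed atom line ", bad[1])
    }
    sym <- vapply(toks, `[`, character(1), 1L)
    xyz <- t(vapply(toks, function(t) {
      suppressWarnings(as.numeric(t[2:4]))
    }, numeric(3)))
    if (!all(is.finite(xyz))) {
      stop("frame ", frame, ": non-finite coordinate")
    }
    z <- if (all(grepl("^[0-9]+$", sym))) as.integer(sym) else {
      tryCatch(symbol_to_z(sym),
               error = function(e) stop("frame ", frame, ": ",
                                        conditionMessage(e)))
    }
    if (format == "extxyz") {
      kv <- .parse_kv(comment)
      if (!"group_id" %in% names(kv)) {
        stop("frame ", frame, ": comment line lacks group_id")
      }
      sid <- if ("structure_id" %in% names(kv)) kv[["structure_id"]] else
        paste0("frame_", frame)
      drop <- c("group_id", "structure_id", "Properties", "Lattice", "pbc")
      prop_kv <- kv[setdiff(names(kv), drop)]
      props <- list()
      for (k in names(prop_kv)) {
        v <- suppressWarnings(as.numeric(prop_kv[[k]]))
        if (!is.na(v)) props[[k]] <- v
      }
      out[[frame]] <- structure_new(sid, kv[["group_id"]], z, xyz, props)
    } else {
      tok1 <- strsplit(trimws(comment), "\\s+")[[1]]
      sid <- if (length(tok1) && nzchar(tok1[1])) tok1[1] else
        paste0("frame_", frame)
      gid <- sid
      props <- list()
      if (!is.null(side)) {
        row <- which(side$structure_id == sid)
        if (length(row) != 1L) {
          stop("frame ", frame, ": structure_id '", sid,
               "' not found (once) in sidecar table")
        }
        gid <- side$group_id[row]
        prop_cols <- setdiff(names(side), c("structure_id", "group_id"))
        for (k in prop_cols) props[[k]] <- as.numeric(side[[k]][row])
      }
      out[[frame]] <- structure_new(sid, gid, z, xyz, props)
    }
    i <- i + 2L + n
  }
  out
}

#' Write structures to an extended-XYZ file
#'
#' The inverse of [read_structures()]: one frame per structure, metadata
#' (`structure_id`, `group_id`, every property) on the comment line.
#'
#' @param structures list of `Structure` objects.
#' @param path output file path.
#' @param digits significant digits for coordinates (default 12, so a
#'   write/read round trip reproduces coordinates to well below 1e-6 A).
#' @return `path`, invisibly.
#' @export
write_structures <- function(structures, path, digits = 12) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in structures) {
    kv <- c(structure_id = s$structure_id, group_id = s$group_id)
    for (k in names(s$properties)) {
      kv[[k]] <- format(s$properties[[k]], digits = 17)
    }
    writeLines(as.character(length(s$atomic_numbers)), con)
    writeLines(.format_kv(kv), con)
    sym <- z_to_symbol(s$atomic_numbers)
    coords <- formatC(s$positions, format = "g", digits = digits)
    writeLines(paste(sym, coords[, 1], coords[, 2], coords[, 3]), con)
  }
  invisible(path)
}

#' Read a delimited property/embedding table
#'
#' Expects a header row; the separator (comma or tab) is inferred from the
#' header line.  Used both for plain-XYZ sidecar metadata and for
#' precomputed-embedding tables.
#'
#' @param path file path.
#' @return a `data.frame` with character id columns.
#' @export
read_property_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("structure_id", "group_id") %in% names(df))) {
    stop("table must contain 'structure_id' and 'group_id' columns")
  }
  df$structure_id <- as.character(df$structure_id)
  df$group_id <- as.character(df$group_id)
  df
}

# ---------------------------------------------------------------------------
# Grouping, splitting, filtering, pair construction
# ---------------------------------------------------------------------------

#' Partition structures into conformer groups
#'
#' One `ConformerGroup` per distinct `group_id`, preserving first-appearance
#' order of groups and file order of members.
#'
#' @param structures list of `Structure` objects.
#' @return list of `ConformerGroup` objects.
#' @export
group_structures <- function(structures) {
  if (!length(structures)) return(list())
  gid <- vapply(structures, function(s) s$group_id, character(1))
  ids <- unique(gid)
  lapply(ids, function(g) conformer_group(g, structures[gid == g]))
}

#' Split conformer groups at the molecule level
#'
#' Whole groups are assigned to train or test by a seeded uniform shuffle, so
#' no configuration of a test molecule is ever seen in training.  The test
#' set receives `round(test_fraction * n_groups)` groups (at least one).
#'
#' @param groups list of `ConformerGroup`.
#' @param test_fraction fraction of molecules held out, in (0, 1);
#'   default 0.05 (a 95/5 split).
#' @param seed integer seed for the shuffle.
#' @return a `SplitResult`: list with `train_groups`, `test_groups`
#'   (character vectors of group ids) and `seed`.
#' @export
split_by_molecule <- function(groups, test_fraction = 0.05, seed = 1L) {
  if (length(groups) < 2L) stop("need at least 2 groups to split")
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("test_fraction must be in (0, 1)")
  }
  ids <- vapply(groups, function(g) g$group_id, character(1))
  n_test <- max(1L, round(test_fraction * length(ids)))
  perm <- with_seed(seed, sample.int(length(ids)))
  test <- sort(ids[perm[seq_len(n_test)]])
  train <- sort(setdiff(ids, test))
  structure(list(train_groups = train, test_groups = test,
                 seed = as.integer(seed)),
            class = "SplitResult")
}

#' Select groups by id
#'
#' @param groups list of `ConformerGroup`.
#' @param ids character vector of group ids to keep.
#' @return the matching subset of `groups`.
#' @export
select_groups <- function(groups, ids) {
  gid <- vapply(groups, function(g) g$group_id, character(1))
  groups[gid %in% ids]
}

#' Filter small groups and cap large ones
#'
#' Mirrors the ensemble-screening protocol for large conformer databases:
#' groups with `size <= min_exclusive` members are dropped (only molecules
#' with more than `min_exclusive` configurations are kept), and larger
#' groups are subsampled without replacement to at most `cap` members by a
#' seeded draw.
#'
#' @param groups list of `ConformerGroup`.
#' @param min_exclusive keep only groups with strictly more members than
#'   this (default 5).
#' @param cap maximum members retained per group (default 11).
#' @param seed integer seed for subsampling.
#' @return filtered/capped list of `ConformerGroup`.
#' @export
filter_and_cap_groups <- function(groups, min_exclusive = 5L, cap = 11L,
                                  seed = 1L) {
  if (min_exclusive < 1L) stop("min_exclusive must be >= 1")
  if (cap < 2L) stop("cap must be >= 2")
  keep <- Filter(function(g) length(g$structures) > min_exclusive, groups)
  with_seed(seed, lapply(keep, function(g) {
    n <- length(g$structures)
    if (n <= cap) return(g)
    idx <- sort(sample.int(n, cap))
    conformer_group(g$group_id, g$structures[idx])
  }))
}

#' Build pair examples from one conformer group
#'
#' Draws up to `budget` distinct unordered member pairs by seeded sampling
#' (all pairs when the budget covers them), emits each once in a seeded
#' random orientation, and labels it by the property comparison: label
#' (1, 0) if the first member's property exceeds the second's, (0, 1) if it
#' is smaller, and (0.5, 0.5) on a tie.  `target_diff` is the signed
#' property difference of the oriented pair.
#'
#' @param group a `ConformerGroup` with at least two members.
#' @param property_name name of the property to compare.
#' @param budget maximum number of pairs (default all pairs).
#' @param seed integer seed for pair sampling and orientation.
#' @param tie_tol absolute tolerance below which two property values count
#'   as tied (default 0: exact comparison).
#' @return list of `PairExample` objects, each a list with `a`, `b`
#'   (Structures), `label` (length-2 numeric), `target_diff`.
#' @export
make_pairs <- function(group, property_name, budget = Inf, seed = 1L,
                       tie_tol = 0) {
  n <- length(group$structures)
  if (n < 2L) stop("group '", group$group_id, "': need >= 2 members")
  vals <- vapply(group$structures, function(s) {
    v <- s$properties[[property_name]]
    if (is.null(v)) {
      stop("structure '", s$structure_id, "' lacks property '",
           property_name, "'")
    }
    as.numeric(v)
  }, numeric(1))
  all_pairs <- utils::combn(n, 2L)
  n_all <- ncol(all_pairs)
  with_seed(seed, {
    if (budget < n_all) {
      all_pairs <- all_pairs[, sample.int(n_all, budget), drop = FALSE]
    }
    flip <- sample(c(TRUE, FALSE), ncol(all_pairs), replace = TRUE)
  })
  lapply(seq_len(ncol(all_pairs)), function(k) {
    i <- all_pairs[1L, k]
    j <- all_pairs[2L, k]
    if (flip[k]) { tmp <- i; i <- j; j <- tmp }
    d <- vals[i] - vals[j]
    label <- if (abs(d) <= tie_tol) c(0.5, 0.5) else if (d > 0) c(1, 0) else
      c(0, 1)
    if (abs(d) <= tie_tol) d <- 0
    structure(list(a = group$structures[[i]], b = group$structures[[j]],
                   label = label, target_diff = d),
              class = "PairExample")
  })
}

#' Build pair examples across many groups
#'
#' Applies [make_pairs()] to every group (per-group seeds derived from
#' `seed`) and concatenates the results.  Pairs are always formed within a
#' group, never across molecules.
#'
#' @inheritParams make_pairs
#' @param groups list of `ConformerGroup`, each with >= 2 members.
#' @return flat list of `PairExample` objects.
#' @export
make_all_pairs <- function(groups, property_name, budget = Inf, seed = 1L,
                           tie_tol = 0) {
  out <- lapply(seq_along(groups), function(i) {
    make_pairs(groups[[i]], property_name, budget = budget,
               seed = seed + i, tie_tol = tie_tol)
  })
  do.call(c, out)
}
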