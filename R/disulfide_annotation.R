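# Disulfide-bond evidence handling: merging sources, counting rules,
# folding-difficulty classification, periplasmic restriction and
# abundance-weighted demand.

QUALIFYING_LOCATIONS <- c("secreted", "secreted outer membrane")
DIFFICULTY_LEVELS <- c("cat1", "cat2", "cat3", "cat4")

normalise_bond_table <- function(tab, source = NULL) {
  need <- c("protein_id", "cys_a", "cys_b")
  if (!all(need %in% names(tab))) {
    stop("bond table needs columns: ", paste(need, collapse = ", "))
  }
  if (is.null(source)) {
    if (!"source" %in% names(tab)) stop("bond table needs a 'source' column or an explicit source label")
    src <- as.character(tab$source)
  } else {
    src <- rep(source, nrow(tab))
  }
  cys_a <- suppressWarnings(as.integer(tab$cys_a))
  raw_b <- toupper(trimws(as.character(tab$cys_b)))
  partner <- ifelse(raw_b %in% c("SELF"), "self",
                    ifelse(raw_b %in% c("OTHER", "INTER", "OTHER-PROTEIN"), "other", "cys"))
  if ("partner" %in% names(tab)) {
    # already-normalised records keep their partner classification
    partner <- ifelse(tab$partner %in% c("self", "other"), tab$partner, partner)
  }
  cys_b <- suppressWarnings(as.integer(ifelse(partner == "cys", raw_b, NA)))
  bad <- is.na(cys_a) | cys_a < 1 |
    (partner == "cys" & (is.na(cys_b) | cys_b < 1))
  if (any(bad)) {
    warning(sprintf("skipping %d bond record(s) with malformed residue indices", sum(bad)))
  }
  out <- data.frame(
    protein_id = as.character(tab$protein_id),
    cys_a = cys_a, cys_b = cys_b, partner = partner,
    source = src, stringsAsFactors = FALSE
  )[!bad, , drop = FALSE]
  # orient intramolecular pairs so cys_a <= cys_b
  swap <- out$partner == "cys" & out$cys_a > out$cys_b
  tmp <- out$cys_a[swap]; out$cys_a[swap] <- out$cys_b[swap]; out$cys_b[swap] <- tmp
  out
}

#' Merge disulfide-bond evidence from several sources
#'
#' All sources identify bonds by protein ID plus the two cysteine residue
#' positions (1-based, Uniprot convention), so records identical in
#' `(protein_id, cys_a, cys_b)` are unified and accumulate the union of
#' their source labels. `cys_b` may also be `"SELF"` (a cysteine bonded to
#' the same cysteine on another copy of the protein, counted 0.5) or
#' `"OTHER"` (a bond to a different protein, intermolecular).
#'
#' @param tables A list of bond tables (data.frames with `protein_id`,
#'   `cys_a`, `cys_b` and either a `source` column or a name in the list
#'   used as the source label).
#' @return A data.frame of unique bond records with columns `protein_id`,
#'   `cys_a`, `cys_b`, `partner` (`"cys"`, `"self"`, `"other"`),
#'   `sources` (semicolon-joined), `n_sources`, `count_value`.
#' @export
merge_bond_sources <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  labels <- names(tables)
  norm <- lapply(seq_along(tables), function(i) {
    src <- if (!is.null(labels) && nzchar(labels[i])) labels[i] else NULL
    normalise_bond_table(tables[[i]], source = src)
  })
  all <- do.call(rbind, norm)
  if (nrow(all) == 0L) {
    return(data.frame(protein_id = character(), cys_a = integer(),
                      cys_b = integer(), partner = character(),
                      sources = character(), n_sources = integer(),
                      count_value = numeric(), stringsAsFactors = FALSE))
  }
  key <- paste(all$protein_id, all$cys_a,
               ifelse(all$partner == "cys", all$cys_b, all$partner), sep = "|")
  first <- !duplicated(key)
  merged <- all[first, c("protein_id", "cys_a", "cys_b", "partner")]
  src_sets <- lapply(split(all$source, key), function(s) sort(unique(s)))
  src_sets <- src_sets[key[first]]
  merged$sources <- vapply(src_sets, paste, "", collapse = ";")
  merged$n_sources <- vapply(src_sets, length, 0L)
  merged$count_value <- ifelse(merged$partner == "self", 0.5,
                               ifelse(merged$partner == "other", 0, 1))
  merged <- merged[order(merged$protein_id, merged$cys_a, merged$cys_b), ]
  rownames(merged) <- NULL
  merged
}

#' Keep bonds supported by at least `min_sources` sources
#'
#' The higher-confidence subset used for kinetic modelling retains bonds
#' described by two or more independent sources.
#'
#' @param records Merged bond records (from [merge_bond_sources()]).
#' @param min_sources Minimum number of supporting sources.
#' @export
confidence_filter <- function(records, min_sources = 2) {
  stopifnot(min_sources >= 1)
  records[records$n_sources >= min_sources, , drop = FALSE]
}

# exact maximum matching on a small cysteine bond graph, by recursion over
# edges; proteins carry at most a handful of bonds so brute force is exact
# and cheap
max_matching_size <- function(edges) {
  if (nrow(edges) == 0L) return(0L)
  e <- edges[1, ]
  rest <- edges[-1, , drop = FALSE]
  skip <- max_matching_size(rest)
  compat <- rest[rest[, 1] != e[1] & rest[, 1] != e[2] &
                   rest[, 2] != e[1] & rest[, 2] != e[2], , drop = FALSE]
  max(skip, 1L + max_matching_size(compat))
}

#' Count disulfide bonds for one protein under the merging rules
#'
#' A cysteine that can bond alternative partners contributes a single
#' disulfide (the largest set of simultaneously formable bonds is
#' counted); a cysteine bonded to its own position on another protein copy
#' contributes 0.5; bonds to other proteins contribute 0.
#'
#' @param records Bond records for a single protein.
#' @return Bond count (real; multiples of 0.5).
#' @export
count_protein_disulfides <- function(records) {
  if (nrow(records) == 0L) return(0)
  if (length(unique(records$protein_id)) > 1L) {
    stop("records must belong to a single protein")
  }
  intra <- records[records$partner == "cys", , drop = FALSE]
  n_intra <- if (nrow(intra)) {
    max_matching_size(unique(cbind(intra$cys_a, intra$cys_b)))
  } else 0L
  n_self <- 0.5 * length(unique(records$cys_a[records$partner == "self"]))
  n_intra + n_self
}

#' Maximum potential disulfides from a protein sequence
#'
#' The number of cysteines divided by two, rounded down.
#'
#' @param sequence One-letter amino-acid sequence.
#' @return Integer count of potential cysteine pairs.
#' @export
max_potential_disulfides <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  valid <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!all(chars %in% valid)) {
    stop("sequence contains non-amino-acid characters: ",
         paste(unique(chars[!chars %in% valid]), collapse = ""))
  }
  as.integer(floor(sum(chars == "C") / 2))
}

#' Classify a protein's disulfide bonds by folding difficulty
#'
#' Categories of increasing misfolding risk: `cat1` proteins have exactly
#' the two cysteines the bond requires, so no mispairing is possible;
#' `cat2` bonds join consecutive cysteines (adjacent in the ordered list
#' of the protein's cysteines) but extra cysteines exist that could
#' mispair; `cat3` bonds join non-consecutive cysteines; `cat4` bonds are
#' intermolecular and are tabulated but excluded from kinetic demand.
#'
#' @param cys_positions Sorted or unsorted 1-based cysteine positions of
#'   the protein.
#' @param bonds Bond records for this protein (columns `cys_a`, `cys_b`,
#'   `partner`).
#' @return List with `per_bond` (category per record) and `protein` (the
#'   hardest non-cat4 category, or `cat4` if only intermolecular bonds).
#' @export
classify_difficulty <- function(cys_positions, bonds) {
  cys <- sort(unique(cys_positions))
  per_bond <- character(nrow(bonds))
  for (i in seq_len(nrow(bonds))) {
    if (bonds$partner[i] != "cys") {
      per_bond[i] <- "cat4"
      next
    }
    a <- bonds$cys_a[i]; b <- bonds$cys_b[i]
    ia <- match(a, cys); ib <- match(b, cys)
    if (is.na(ia) || is.na(ib)) {
      stop(sprintf("bond (%d, %d) references a residue missing from the cysteine list", a, b))
    }
    per_bond[i] <-
      if (length(cys) == 2L) "cat1"
      else if (abs(ib - ia) == 1L) "cat2"
      else "cat3"
  }
  intra <- per_bond[per_bond != "cat4"]
  protein <- if (length(intra)) intra[which.max(match(intra, DIFFICULTY_LEVELS))]
             else if (length(per_bond)) "cat4" else NA_character_
  list(per_bond = per_bond, protein = protein)
}

#' Build per-protein disulfide profiles
#'
#' Combines merged bond records with the per-protein cysteine inventory
#' into one row per protein carrying the bond count, folding-difficulty
#' category and (optionally) subcellular location.
#'
#' @param records Merged bond records.
#' @param cys_table data.frame with `protein_id` and `cys_positions`
#'   (comma-separated 1-based positions), covering every protein in
#'   `records`.
#' @param location_table Optional data.frame with `protein_id`,
#'   `location`.
#' @return data.frame with one row per protein: `protein_id`, `n_cys`,
#'   `bond_count`, `category`, `location`. The classified bond records are
#'   attached as attribute `"records"` (with a `category` column added).
#' @export
disulfide_profiles <- function(records, cys_table, location_table = NULL) {
  cys_list <- lapply(strsplit(as.character(cys_table$cys_positions), ","),
                     function(x) as.integer(trimws(x)))
  names(cys_list) <- cys_table$protein_id
  ids <- unique(records$protein_id)
  missing <- setdiff(ids, names(cys_list))
  if (length(missing)) {
    stop("cysteine positions missing for protein(s): ",
         paste(head(missing, 5), collapse = ", "))
  }
  records$category <- NA_character_
  rows <- lapply(ids, function(id) {
    sub <- records[records$protein_id == id, , drop = FALSE]
    cls <- classify_difficulty(cys_list[[id]], sub)
    records$category[records$protein_id == id] <<- cls$per_bond
    data.frame(protein_id = id,
               n_cys = length(unique(cys_list[[id]])),
               bond_count = count_protein_disulfides(sub),
               category = cls$protein,
               stringsAsFactors = FALSE)
  })
  prof <- do.call(rbind, rows)
  prof$location <- NA_character_
  if (!is.null(location_table)) {
    prof$location <- location_table$location[match(prof$protein_id,
                                                   location_table$protein_id)]
  }
  attr(prof, "records") <- records
  prof
}

#' Restrict profiles to periplasmic proteins
#'
#' Potential Dsb substrates are the proteins annotated as `"secreted"` or
#' `"secreted outer membrane"` in the location table.
#'
#' @param profiles Output of [disulfide_profiles()].
#' @param location_table Optional data.frame `protein_id` -> `location`;
#'   if omitted, the `location` column already on the profiles is used.
#' @param on_missing `"drop"` (default) or `"keep"` for proteins without a
#'   location annotation (kept entries trigger a warning).
#' @export
periplasmic_subset <- function(profiles, location_table = NULL,
                               on_missing = c("drop", "keep")) {
  on_missing <- match.arg(on_missing)
  loc <- if (!is.null(location_table)) {
    location_table$location[match(profiles$protein_id, location_table$protein_id)]
  } else {
    profiles$location
  }
  unknown <- is.na(loc)
  if (any(unknown) && on_missing == "keep") {
    warning(sprintf("%d protein(s) lack location annotation; kept", sum(unknown)))
  }
  keep <- loc %in% QUALIFYING_LOCATIONS | (unknown & on_missing == "keep")
  out <- profiles[keep, , drop = FALSE]
  rec <- attr(profiles, "records")
  if (!is.null(rec)) {
    attr(out, "records") <- rec[rec$protein_id %in% out$protein_id, , drop = FALSE]
  }
  out
}

#' Abundance-weighted oxidative folding demand
#'
#' Multiplies each protein's disulfide-bond count by its copies per cell
#' and totals the result per folding-difficulty category. Intermolecular
#' (cat4) bonds are tabulated but excluded from kinetic demand downstream.
#'
#' @param profiles Per-protein profiles (normally the periplasmic subset).
#' @param proteome A `quantitative_proteome` supplying copies per cell;
#'   proteins absent from it contribute zero (a message reports how many).
#' @return A `folding_demand` data.frame: `category`, `bonds_per_cell`,
#'   `protein_copies`, with the condition label as attribute.
#' @export
folding_demand <- function(profiles, proteome) {
  stopifnot(inherits(proteome, "quantitative_proteome"))
  copies <- proteome$abundances[profiles$protein_id]
  absent <- is.na(copies)
  if (any(absent)) {
    message(sprintf("%d disulfide protein(s) not quantified in '%s'; contributing 0",
                    sum(absent), proteome$condition_label))
    copies[absent] <- 0
  }
  cat <- factor(profiles$category, levels = DIFFICULTY_LEVELS)
  out <- data.frame(
    category = DIFFICULTY_LEVELS,
    bonds_per_cell = as.numeric(tapply(profiles$bond_count * copies, cat, sum,
                                       default = 0)),
    protein_copies = as.numeric(tapply(copies, cat, sum, default = 0)),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("folding_demand", class(out)),
            condition_label = proteome$condition_label)
}

#' Kinetic demand vector from a folding-demand table
#'
#' @param demand A `folding_demand`.
#' @return Named vector `c(cat1=, cat2=, cat3=)` of bonds per cell
#'   (intermolecular bonds excluded).
#' @export
demand_vector <- function(demand) {
  stopifnot(inherits(demand, "folding_demand"))
  setNames(demand$bonds_per_cell[match(c("cat1", "cat2", "cat3"),
                                       demand$category)],
           c("cat1", "cat2", "cat3"))
}

#' Read a delimited bond table
#' @param path File path with header `protein_id`, `cys_a`, `cys_b` and
#'   optionally `source`.
#' @param source Source label applied to every record if the table has no
#'   `source` column.
#' @param sep Field separator.
#' @export
read_bond_table <- function(path, source = NULL, sep = "\t") {
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  normalise_bond_table(tab, source = source)
}

#' Read a wide per-source disulfide sheet
#'
#' Supports the layout of a curated disulfide data sheet: one row per
#' bond with `protein_id`, `cys_a`, `cys_b` and one 0/1 indicator column
#' per evidence source.
#'
#' @param path File path.
#' @param source_cols Names of the indicator columns; defaults to every
#'   column after `cys_b`.
#' @param sep Field separator.
#' @return Merged bond records (as from [merge_bond_sources()]).
#' @export
read_dsb_sheet <- function(path, source_cols = NULL, sep = "\t") {
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  base_cols <- c("protein_id", "cys_a", "cys_b")
  if (is.null(source_cols)) source_cols <- setdiff(names(tab), base_cols)
  if (!length(source_cols)) stop("no source indicator columns found")
  tables <- lapply(source_cols, function(sc) {
    tab[as.logical(tab[[sc]]) %in% TRUE, base_cols, drop = FALSE]
  })
  names(tables) <- source_cols
  merge_bond_sources(tables)
}

#' Write a category summary table
#' @param demand A `folding_demand`.
#' @param path Output TSV path.
#' @export
write_category_summary <- function(demand, path) {
  write.table(demand, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
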