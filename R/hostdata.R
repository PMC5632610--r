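#' Read a species-level host-record table
#'
#' Loads a delimited table of larval host records with columns
#' `moth_species`, `genus_taxon`, `plant_family`, `plant_order` (one row per
#' record). Records are validated (no empty cells) and de-duplicated on the
#' `(moth_species, plant_order)` pair, since repeated family-level records
#' within one plant order carry no extra information for order-level host
#' diversity.
#'
#' @param path Path to the delimited file (header row required).
#' @param delim Field delimiter, tab by default.
#' @return A tibble of validated, de-duplicated host records.
#' @export
read_host_records <- function(path, delim = "\t") {
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  as_host_records(raw)
}

#' Validate an in-memory host-record table
#'
#' @param records A data frame with the four host-record columns.
#' @return A tibble of validated, de-duplicated host records.
#' @export
as_host_records <- function(records) {
  needed <- c("moth_species", "genus_taxon", "plant_family", "plant_order")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  records <- as_tibble(records)[needed]
  records <- dplyr::mutate(records, dplyr::across(
    dplyr::everything(), ~ trimws(as.character(.x))
  ))
  if (nrow(records) == 0) {
    warn("host-record table is empty")
    return(records)
  }
  blank <- !stats::complete.cases(records) |
    apply(records == "", 1, any)
  if (any(blank)) {
    abort(paste0("empty cell(s) in host-record row(s): ",
                 paste(head(which(blank), 5), collapse = ", ")))
  }
  n0 <- nrow(records)
  records <- dplyr::distinct(records, .data$moth_species, .data$plant_order,
                             .keep_all = TRUE)
  if (nrow(records) < n0) {
    inform(paste0("de-duplicated host records: ", n0, " rows in, ",
                  nrow(records), " retained"))
  }
  records
}

#' Derive genus-level host-use traits
#'
#' Collapses species-level host records into per-taxon traits: host diversity
#' `hd` (number of distinct plant orders used by any species of the taxon),
#' `max_polyphagy` (orders used by the single most polyphagous species), the
#' binary polyphagy codings `poly3`/`poly7` (does any species feed on at least
#' 3, resp. 7, orders), and externally supplied species richness. Plant-order
#' names are matched case-insensitively after trimming.
#'
#' @param records Host-record table (see [read_host_records()]).
#' @param richness Species richness per taxon: a named numeric vector, or a
#'   data frame with columns `taxon` and `n_species`. Every taxon present in
#'   `records` must appear.
#' @return A tibble with columns `taxon`, `n_species`, `host_orders`
#'   (list-column), `hd`, `max_polyphagy`, `poly3`, `poly7`.
#' @examples
#' rec <- tibble::tibble(
#'   moth_species = c("s1", "s1", "s2"), genus_taxon = "G",
#'   plant_family = "F", plant_order = c("Fabales", "Rosales", "Fabales"))
#' derive_genus_traits(rec, c(G = 4))
#' @export
derive_genus_traits <- function(records, richness) {
  records <- as_host_records(records)
  richness <- richness_lookup(richness)
  taxa <- unique(records$genus_taxon)
  absent <- setdiff(taxa, names(richness))
  if (length(absent)) {
    abort(paste0("taxa missing from the richness table: ",
                 paste(absent, collapse = ", ")))
  }
  canon <- function(x) tolower(trimws(x))
  per_species <- records |>
    dplyr::mutate(order_key = canon(.data$plant_order)) |>
    dplyr::group_by(.data$genus_taxon, .data$moth_species) |>
    dplyr::summarise(breadth = dplyr::n_distinct(.data$order_key), .groups = "drop")
  traits <- records |>
    dplyr::mutate(order_key = canon(.data$plant_order)) |>
    dplyr::group_by(.data$genus_taxon) |>
    dplyr::summarise(
      host_orders = list(sort(unique(.data$plant_order[!duplicated(.data$order_key)]))),
      hd = dplyr::n_distinct(.data$order_key),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      dplyr::summarise(dplyr::group_by(per_species, .data$genus_taxon),
                       max_polyphagy = max(.data$breadth), .groups = "drop"),
      by = "genus_taxon"
    ) |>
    dplyr::transmute(
      taxon = .data$genus_taxon,
      n_species = as.integer(richness[.data$genus_taxon]),
      host_orders = .data$host_orders,
      hd = as.integer(.data$hd),
      max_polyphagy = as.integer(.data$max_polyphagy),
      poly3 = as.integer(.data$max_polyphagy >= 3L),
      poly7 = as.integer(.data$max_polyphagy >= 7L)
    ) |>
    dplyr::arrange(.data$taxon)
  stopifnot(all(traits$hd >= traits$max_polyphagy),
            all(traits$max_polyphagy >= 1),
            all(traits$n_species >= 1))
  traits
}

richness_lookup <- function(richness) {
  if (is.data.frame(richness)) {
    if (!all(c("taxon", "n_species") %in% names(richness))) {
      abort("richness data frame needs columns `taxon` and `n_species`")
    }
    richness <- setNames(richness$n_species, richness$taxon)
  }
  if (is.null(names(richness)) || any(!nzchar(names(richness)))) {
    abort("richness must be named by taxon")
  }
  if (any(richness < 1)) abort("every taxon must have n_species >= 1")
  richness
}

#' Code a binary polyphagy trait at a threshold
#'
#' A taxon is coded 1 when at least one of its species feeds on `threshold`
#' or more plant orders (so `threshold = 3` and `7` give the standard
#' "3+ orders" and "7+ orders" codings).
#'
#' @param traits Genus-trait table from [derive_genus_traits()].
#' @param threshold Integer threshold `k >= 1` on `max_polyphagy`.
#' @return Named integer vector (taxon -> 0/1), ready for the signal tests.
#' @export
code_binary_trait <- function(traits, threshold) {
  stopifnot(threshold >= 1)
  setNames(as.integer(traits$max_polyphagy >= threshold), traits$taxon)
}

#' Taxon-by-order host-use matrix
#'
#' Binary matrix with one row per taxon and one column per plant order; cell
#' 1 means some species of the taxon is recorded on that order. Column sums
#' give per-order taxon counts, used to rank orders and pick the most widely
#' used ones for trait tracing.
#'
#' @param traits Genus-trait table from [derive_genus_traits()].
#' @param orders Character vector of plant-order names (columns). Unknown
#'   names are allowed (all-zero column) but warned about.
#' @return Integer matrix, `rownames` = taxa, `colnames` = `orders`.
#' @export
order_usage_matrix <- function(traits, orders) {
  stopifnot(length(orders) > 0)
  canon <- function(x) tolower(trimws(x))
  m <- vapply(orders, function(o) {
    vapply(traits$host_orders, function(ho) as.integer(canon(o) %in% canon(ho)), 1L)
  }, integer(nrow(traits)))
  m <- matrix(m, nrow = nrow(traits), dimnames = list(traits$taxon, orders))
  zero <- colnames(m)[colSums(m) == 0]
  if (length(zero)) {
    warn(paste0("order(s) used by no taxon: ", paste(zero, collapse = ", ")))
  }
  m
}

#' Rank plant orders by number of taxa using them
#'
#' @param traits Genus-trait table.
#' @param n How many top orders to return (default 10).
#' @return Tibble with columns `plant_order` and `n_taxa`, most-used first.
#' @export
top_host_orders <- function(traits, n = 10) {
  tibble(plant_order = unlist(traits$host_orders)) |>
    dplyr::count(.data$plant_order, name = "n_taxa", sort = TRUE) |>
    dplyr::slice_head(n = n)
}
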