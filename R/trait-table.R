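#' Validate a long-format trait table
#'
#' Checks the schema and internal consistency of a trait table: required
#' columns, no duplicate fragment x trait measurements, every tank assigned
#' to exactly one treatment, known treatment labels, and finite values.
#'
#' @param table A data.frame with columns `fragment_id`, `genotype_id`,
#'   `treatment`, `tank_id`, `trait_name`, `value`.
#' @return The table, invisibly, with factors normalized to character and
#'   treatments checked against [treatment_levels()]. Problems abort with a
#'   message naming the offending rows/tanks.
#' @export
validate_trait_table <- function(table) {
  required <- c("fragment_id", "genotype_id", "treatment", "tank_id",
                "trait_name", "value")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         "; expected schema: ", paste(required, collapse = ", "))
  }
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  for (col in setdiff(required, "value")) table[[col]] <- as.character(table[[col]])
  table$value <- as.numeric(table$value)

  bad_trt <- setdiff(unique(table$treatment), treatment_levels())
  if (length(bad_trt) > 0) {
    stop("unknown treatment label(s): ", paste(bad_trt, collapse = ", "),
         " (expected ", paste(treatment_levels(), collapse = ", "), ")")
  }

  key <- paste(table$fragment_id, table$trait_name, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1]
    stop("duplicate (fragment_id, trait_name) pair at row ", dup, ": ",
         table$fragment_id[dup], " / ", table$trait_name[dup])
  }

  tank_map <- unique(table[c("tank_id", "treatment")])
  dup_tank <- tank_map$tank_id[duplicated(tank_map$tank_id)]
  if (length(dup_tank) > 0) {
    stop("tank(s) assigned to more than one treatment: ",
         paste(unique(dup_tank), collapse = ", "))
  }

  if (any(!is.finite(table$value))) {
    bad <- which(!is.finite(table$value))
    stop("non-finite value(s) at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  invisible(table)
}

#' Read a trait table from CSV
#'
#' @param path Path to a CSV file with the long-format schema of
#'   [validate_trait_table()].
#' @return A validated trait table data.frame.
#' @export
read_trait_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trait_table(tab)
  tab
}

#' Write a trait table to CSV
#'
#' @param table A trait table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path) {
  cols <- c("fragment_id", "genotype_id", "treatment", "tank_id",
            "trait_name", "value")
  utils::write.csv(as.data.frame(table)[cols], path, row.names = FALSE)
  invisible(path)
}

#' Trait names present in a table
#' @param table A trait table.
#' @return Character vector of trait names, in order of first appearance.
#' @export
trait_names <- function(table) unique(table$trait_name)

# internal: subset one trait, with factors in canonical order
.trait_subset <- function(table, trait) {
  stopifnot(trait %in% table$trait_name)
  d <- table[table$trait_name == trait, , drop = FALSE]
  d$treatment <- factor(d$treatment, levels = treatment_levels())
  d$treatment <- droplevels(d$treatment)
  d$genotype_id <- factor(d$genotype_id)
  d$tank_id <- factor(d$tank_id)
  d
}
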