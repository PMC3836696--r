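# End-to-end orchestration over a directory of PDB biounits: parse ->
# normalize -> SASA -> contacts -> sites -> dedup -> frequencies ->
# propensities -> ratios, with TSV report writers and a run manifest.

#' Configuration for a full analysis run
#'
#' Collects every threshold of the analysis: 4.0 A contact cutoff, 3.5 A
#' hydrogen-bond cutoff, the SASA surface cutoff (5.0 or 0.5 Angstrom^2),
#' probe radius, and the resampling settings.
#'
#' @param structures_dir Directory of PDB files (`*.pdb`).
#' @param annotations Path to a ligand-annotation TSV, or a data frame
#'   (see [read_ligand_annotations()]), or NULL.
#' @param out_dir Output directory for the report TSVs and manifest.
#' @param contact_cutoff,hbond_cutoff Distance cutoffs in Angstrom; the
#'   hydrogen-bond cutoff must not exceed the contact cutoff.
#' @param sasa_cutoff Surface-residue SASA cutoff in Angstrom^2.
#' @param probe_radius,n_sphere_points SASA engine parameters.
#' @param top_k_exclude Exclude sites of the k most frequent ligands per
#'   validity class (0 = keep all).
#' @param seed Integer seed for any resampling stages.
#' @return A `bp_run_config` list.
#' @export
run_config <- function(structures_dir, annotations = NULL, out_dir,
                       contact_cutoff = 4.0, hbond_cutoff = 3.5,
                       sasa_cutoff = 5.0, probe_radius = 1.4,
                       n_sphere_points = 960L, top_k_exclude = 0L,
                       seed = 1L) {
  stopifnot(contact_cutoff > 0, hbond_cutoff > 0,
            hbond_cutoff <= contact_cutoff, sasa_cutoff >= 0)
  structure(list(structures_dir = structures_dir, annotations = annotations,
                 out_dir = out_dir, contact_cutoff = contact_cutoff,
                 hbond_cutoff = hbond_cutoff, sasa_cutoff = sasa_cutoff,
                 probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 top_k_exclude = as.integer(top_k_exclude),
                 seed = as.integer(seed)),
            class = "bp_run_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full binding-site composition analysis
#'
#' Executes every stage on all structures in the configured directory and
#' writes: a per-site table, a dataset summary, raw and surface contact
#' summaries, per-configuration frequencies/propensities, valid/invalid
#' ratios (where both classes exist), and a JSON manifest recording the
#' configuration, seed and per-stage counters. Any stage error aborts with
#' the stage name and structure id.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the per-structure objects and report
#'   tables.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "bp_run_config"))
  files <- sort(list.files(cfg$structures_dir, pattern = "\\.pdb$",
                           full.names = TRUE))
  if (!length(files)) stop("no PDB files in ", cfg$structures_dir)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- cfg$annotations
  if (is.character(ann)) ann <- read_ligand_annotations(ann)
  params <- sasa_params(cfg$probe_radius, cfg$n_sphere_points)

  surfaces <- list()
  all_sites <- list()
  counters <- list()
  for (f in files) {
    id <- sub("\\.pdb$", "", basename(f))
    stage <- "parse"
    result <- tryCatch({
      s <- parse_structure(f, annotations = ann, structure_id = id)
      stage <- "normalize"; s <- normalize_structure(s)
      stage <- "sasa"; surf <- compute_sasa(s, params)
      stage <- "sites"
      sites <- build_all_sites(s, surf, cfg$sasa_cutoff,
                               cfg$contact_cutoff, cfg$hbond_cutoff)
      built <- length(sites)
      sites <- sites[vapply(sites, function(x) x$n_residues, 1L) > 0]
      stage <- "dedup"; nr <- deduplicate_sites(sites)
      list(surf = surf, sites = sites, nr = nr, built = built)
    }, error = function(e) {
      stop("stage '", stage, "' failed for structure '", id, "': ",
           conditionMessage(e), call. = FALSE)
    })
    surfaces[[id]] <- result$surf
    all_sites <- c(all_sites, result$nr)
    counters[[id]] <- list(
      sites_built = result$built,
      sites_nonempty = length(result$sites),
      sites_after_dedup = length(result$nr),
      sites_empty_surface = sum(vapply(result$nr,
                                       function(x) x$empty_surface, TRUE)))
  }

  if (cfg$top_k_exclude > 0)
    all_sites <- exclude_top_ligands(all_sites, cfg$top_k_exclude)

  # Per-site table.
  site_tab <- do.call(rbind, lapply(all_sites, function(st) data.frame(
    structure_id = st$structure_id, het_code = st$het_code,
    chain = st$chain, resno = st$resno, validity = st$validity,
    n_residues = st$n_residues, site_sasa = st$site_sasa,
    empty_surface = st$empty_surface,
    residues = paste(st$residues$resname, collapse = ","),
    stringsAsFactors = FALSE)))
  write_tsv(site_tab, file.path(cfg$out_dir, "sites.tsv"))

  summary_tab <- dataset_summary(all_sites, surfaces, cfg$sasa_cutoff)
  write_tsv(summary_tab, file.path(cfg$out_dir, "dataset_summary.tsv"))

  raw_contacts <- summarize_contacts(all_sites)
  write_tsv(raw_contacts, file.path(cfg$out_dir, "contacts_raw.tsv"))
  surf_contacts <- tryCatch(
    summarize_contacts(all_sites, surface_cutoff = cfg$sasa_cutoff),
    error = function(e) NULL)
  if (!is.null(surf_contacts))
    write_tsv(surf_contacts, file.path(cfg$out_dir, "contacts_surface.tsv"))

  # Propensities per (class, validity) configuration that has data.
  usable <- all_sites[!vapply(all_sites, function(x) x$empty_surface, TRUE)]
  props <- list()
  for (cls in c("SC", "BB_only")) {
    for (v in unique(vapply(usable, function(x) x$validity, ""))) {
      p <- tryCatch(site_propensity(usable, surfaces, cls, v,
                                    cfg$sasa_cutoff),
                    error = function(e) NULL)
      if (!is.null(p)) {
        props[[paste(cls, v, sep = "_")]] <- p
        write_tsv(p, file.path(cfg$out_dir,
                               paste0("propensity_", cls, "_", v, ".tsv")))
      }
    }
  }
  if (!is.null(props$SC_valid) && !is.null(props$SC_invalid)) {
    write_tsv(propensity_ratio(props$SC_valid, props$SC_invalid),
              file.path(cfg$out_dir, "propensity_ratio_SC.tsv"))
  }

  manifest <- list(
    config = cfg[setdiff(names(cfg), "annotations")],
    seed = cfg$seed,
    structures = names(surfaces),
    counters = counters,
    n_sites = length(all_sites))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(list(surfaces = surfaces, sites = all_sites,
                 summary = summary_tab, contacts_raw = raw_contacts,
                 contacts_surface = surf_contacts, propensities = props))
}
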