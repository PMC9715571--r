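#!/usr/bin/env Rscript
# Optional analysis of publicly deposited WTAP / WTAP-VIRMA coordinate
# models. Requires local copies of the deposited files (not bundled;
# fetch the WTAP crystal dimer and the WTAP-VIRMA cryo-EM model from the
# PDB yourself):
#
#   Rscript scripts/paper_numbers.R --crystal crystal.cif --cryoem cryoem.cif \
#       [--links identifications.csv] [--out results/paper_numbers.json]
#
# Computes, with package defaults:
#   * WTAP dimer crystal-vs-cryoEM CA superposition RMSD over the common
#     residue pairing (both homodimer chain assignments tried)
#   * buried areas, hydrogen bonds and salt bridges for the three
#     WTAP-VIRMA interfaces (both delta/2 and delta conventions)
#   * principal CA extents of the WTAP-VIRMA selection
#   * crosslink counts at FDR <= 0.05 when an identification table in the
#     package CSV dialect is supplied

suppressPackageStartupMessages(library(xlassemble))

args <- commandArgs(trailingOnly = TRUE)
get_opt <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
crystal_path <- get_opt("--crystal")
cryoem_path <- get_opt("--cryoem")
links_path <- get_opt("--links")
out_path <- get_opt("--out", "results/paper_numbers.json")
if (is.null(crystal_path) || is.null(cryoem_path))
  stop("supply --crystal and --cryoem coordinate files (PDB or mmCIF)")

results <- list()

crystal <- read_structure(crystal_path)
cryoem <- read_structure(cryoem_path)
cat("crystal:", paste(unique(crystal$atoms$chain), collapse = ","), "\n")
cat("cryoem: ", paste(unique(cryoem$atoms$chain), collapse = ","), "\n")

# WTAP dimer chains: crystal A/B; in the cryo-EM model the two WTAP
# copies are the two shortest chains (override here if relabelled)
wtap_crystal <- get_opt("--crystal-chains", "A,B")
wtap_cryoem <- get_opt("--cryoem-chains", NULL)
if (is.null(wtap_cryoem)) {
  sizes <- sort(table(cryoem$atoms$chain))
  wtap_cryoem <- paste(names(sizes)[1:2], collapse = ",")
}
cc <- strsplit(wtap_crystal, ",")[[1]]
ce <- strsplit(wtap_cryoem, ",")[[1]]
pairing <- c(ce[1], ce[2]); names(pairing) <- cc

sup <- superpose_models(crystal, cryoem, pairing, try_swap = TRUE)
cat(sprintf("WTAP dimer superposition: RMSD %.2f A over %d CA (%s)\n",
            sup$rmsd, sup$n_atoms,
            if (sup$swapped) "swapped assignment" else "direct assignment"))
results$wtap_dimer_rmsd <- list(value = sup$rmsd, n = sup$n_atoms)

# interfaces: WTAP_A / WTAP_B vs VIRMA per the declared residue ranges
virma_chain <- setdiff(unique(cryoem$atoms$chain), ce)[1]
ifaces <- list(
  interface1 = list(wtap = ce[1], wtap_res = c(205:224, 244),
                    virma_res = 452:660),
  interface2 = list(wtap = ce[2], wtap_res = c(177:200, 214:221),
                    virma_res = 657:1030),
  interface3 = list(wtap = ce[2], wtap_res = 214:221,
                    virma_res = 494:497))
for (nm in names(ifaces)) {
  d <- ifaces[[nm]]
  ga <- select_atoms(cryoem, chains = d$wtap, resno = d$wtap_res)
  gb <- select_atoms(cryoem, chains = virma_chain, resno = d$virma_res)
  if (!length(ga) || !length(gb)) {
    cat(nm, ": selection empty, skipped\n"); next
  }
  rep <- interface_report(cryoem, nm, ga, gb)
  cat(sprintf("%s: buried %.1f A^2 (delta %.1f); %d hbond(s), %d salt bridge(s)\n",
              nm, rep$buried_area, rep$delta_sasa, nrow(rep$hbonds),
              nrow(rep$salt_bridges)))
  results[[paste0(nm, "_buried_area")]] <-
    list(value = rep$buried_area, n = length(ga) + length(gb))
  results[[paste0(nm, "_delta_sasa")]] <-
    list(value = rep$delta_sasa, n = length(ga) + length(gb))
  if (nrow(rep$salt_bridges))
    print(rep$salt_bridges)
}

dims <- principal_dimensions(cryoem)
cat(sprintf("principal CA extents: %.0f x %.0f x %.0f A\n",
            dims[1], dims[2], dims[3]))
results$dim_1 <- list(value = dims[1], n = nrow(cryoem$atoms))
results$dim_2 <- list(value = dims[2], n = nrow(cryoem$atoms))
results$dim_3 <- list(value = dims[3], n = nrow(cryoem$atoms))

if (!is.null(links_path)) {
  xl <- parse_crosslinks(links_path, fdr_threshold = 0.05)
  kinds <- ifelse(xl$links$protein_a == xl$links$protein_b,
                  "intra", "inter")
  cat(sprintf("crosslinks at FDR <= 0.05: %d total, %d inter-subunit, %d intra-subunit\n",
              nrow(xl$links), sum(kinds == "inter"),
              sum(kinds == "intra")))
  results$n_links_total <- list(value = nrow(xl$links),
                                n = nrow(xl$links))
  results$n_links_inter <- list(value = sum(kinds == "inter"),
                                n = nrow(xl$links))
}

dir.create(dirname(out_path), recursive = TRUE, showWarnings = FALSE)
jsonlite::write_json(results, out_path, auto_unbox = TRUE, digits = NA)
cat("wrote", out_path, "\n")
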