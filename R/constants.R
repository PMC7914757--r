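#' Vertebrate group registry
#'
#' Letter codes for the vertebrate groups used throughout the package, in the
#' conventional ordering from placental mammals (A) to cartilaginous fishes
#' (N). Cyclostomes are carried under the separate code \code{"CY"} because
#' they are handled by dedicated naming rules rather than the incremental
#' harmonization orders.
#'
#' @return Named character vector mapping letter code to group name.
#' @export
#' @examples
#' vertebrateGroups()[["M"]]
vertebrateGroups <- function() {
  c(A = "Placental mammals",
    B = "Marsupials",
    C = "Monotremata",
    D = "Aves",
    E = "Crocodylia",
    F = "Testudines",
    G = "Squamata",
    H = "Amphibia",
    I = "Lobe-finned fish",
    J = "Chondrostei-Polypteriformes",
    K = "Chondrostei-Acipenseriformes",
    L = "Holostei",
    M = "Teleostei",
    N = "Chondrichthyes",
    CY = "Cyclostomata")
}

.MAMMAL_GROUPS <- c("A", "B", "C")

## Kyte-Doolittle hydropathy scale (one value per amino acid).
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
         E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
         M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
         Y = -1.3, V = 4.2)

## One deterministic codon per amino acid, used when reverse-translating the
## simulator's template protein. Cysteine is TGT so motif ablation (-> AGC,
## serine) is a two-substitution change, as in degenerate real cases.
.CODON_OF <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
               Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
               L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCA",
               S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

.STOP_CODONS <- c("TAA", "TAG", "TGA")

## residues accepted in simulated transmembrane helices (strongly
## hydrophobic, cysteine excluded so motif signatures stay unambiguous)
.TM_ALLOWED <- c("A", "F", "I", "L", "M", "V")

.aaOrderJTT <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
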