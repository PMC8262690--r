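Package: foldnets
Title: Hydrophobic Clusters, Hydrogen-Bond and Salt-Bridge Networks, and
    Contact Maps for Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Offline structural analyses of protein interaction networks
    from PDB coordinates. Detects isoleucine/leucine/valine (ILV)
    hydrophobic clusters from atomic contact areas computed with a
    Fibonacci-lattice surface-section algorithm, sidechain hydrogen-bond
    networks under the Baker-Hubbard geometric criterion after
    deterministic pH-7 protonation, salt-bridge networks from
    acidic-oxygen/basic-nitrogen distances, sequence charge-patterning
    metrics (FCR and kappa), and minimum-distance residue contact maps.
    All results are returned as tibbles, with tidy()/glance() methods and
    ggplot2 autoplot() visualisations, plus a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
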