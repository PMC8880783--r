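Place user-downloaded coordinate files of the nonbifurcating homolog
entries here (PDB or mmCIF; filenames containing the accession, e.g.
3iam.pdb / 3iam.cif and 6tga.pdb / 6tga.cif) before installing the
package, or point options(cofanet.homolog_dir = ...) at a directory
containing them. The package does not fetch structures itself. These
files enable the homolog accessory-cluster gap checks in the test suite
and the corresponding entries of scripts/acceptance.R.
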