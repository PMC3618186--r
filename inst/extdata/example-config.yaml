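# Example run configuration for sedeq::readRunConfig().
# Species table: coiled-coil fragments with SEDNTERP-derived partial
# specific volumes; extinctions follow the 230-nm per-residue rule when
# only n_residues is given. Masses marked here are theoretical monomer
# masses where established.
pka_set: emboss
buffer:
  density_g_ml: 1.005
  temperature_K: 277
  nacl_M: 0.137
  pH: 7.4
species:
  - name: IC1-44
    mass_da: 5470
    vbar: 0.736
    n_residues: 44
  - name: IC1-124
    mass_da: 13880
    vbar: 0.731
    n_residues: 124
  - name: CC1B
    mass_da: 17000
    vbar: 0.726
    n_residues: 149
fit:
  n_starts: 5
  delta_chi_square: 4.0
output_dir: out
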