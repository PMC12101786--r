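Place the real MNTB-LSO QC recordings here to enable the data-dependent
acceptance test:

  s2_qc_data.xlsx  - spreadsheet of 16 recordings (50 Hz, 3000 stimuli),
                     long or one-column-per-recording layout
  s2_qc_data.csv   - equivalent csv export (either layout)

The recordings are not redistributable with the package sources.
Reinstall the package after adding a file so system.file() can find it.
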