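* Synthetic stand-in AAindex1 file bundled with the thermodet package.
* It carries the six accessions the pipeline expects, but the numeric
* values are stand-in scales of the same family as each published entry
* (e.g. Kyte-Doolittle hydropathy for the hydrophobicity slot, residue
* molecular weights for the molecular-weight slot, Grantham polarity for
* the polarity slot).  For analyses of real data obtain the published
* entries from the AAindex database and pass that file instead.
H COWR900101
D Hydrophobicity index (synthetic stand-in: Kyte-Doolittle hydropathy)
R SYNTHETIC STAND-IN
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    1.8    -4.5    -3.5    -3.5     2.5    -3.5    -3.5    -0.4    -3.2     4.5
    3.8    -3.9     1.9     2.8    -1.6    -0.8    -0.7    -0.9    -1.3     4.2
//
H FASG760101
D Molecular weight (residue molecular weight, Da)
R SYNTHETIC STAND-IN
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
  89.09  174.20  132.12  133.10  121.16  146.15  147.13   75.07  155.16  131.17
 131.17  146.19  149.21  165.19  115.13  105.09  119.12  204.23  181.19  117.15
//
H GRAR740102
D Polarity (synthetic stand-in: Grantham polarity)
R SYNTHETIC STAND-IN
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    8.1    10.5    11.6    13.0     5.5    10.5    12.3     9.0    10.4     5.2
    4.9    11.3     5.7     5.2     8.0     9.2     8.6     5.4     6.2     5.9
//
H TAKK010101
D Side chain contribution to protein stability (synthetic stand-in: residue volume)
R SYNTHETIC STAND-IN
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   88.6   173.4   114.1   111.1   108.5   143.8   138.4    60.1   153.2   166.7
  166.7   168.6   162.9   189.9   112.7    89.0   116.1   227.8   193.6   140.0
//
H VINM940101
D Normalized flexibility parameters, B-values (synthetic stand-in)
R SYNTHETIC STAND-IN
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
  0.984   1.008   1.048   1.068   0.906   1.037   1.094   1.031   0.950   0.927
  0.935   1.102   0.952   0.915   1.049   1.046   0.997   0.904   0.929   0.931
//
H ZHOH040103
D Buriability (synthetic stand-in: fraction of residues at least 95% buried)
R SYNTHETIC STAND-IN
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   0.38    0.01    0.12    0.15    0.45    0.07    0.18    0.36    0.17    0.60
   0.45    0.03    0.40    0.50    0.18    0.22    0.23    0.27    0.15    0.54
//
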