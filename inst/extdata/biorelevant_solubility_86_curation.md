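# Curation notes for biorelevant_solubility_86.csv

The source table prints one, two or three apparent-solubility values per
compound without marking which medium a missing value belongs to. Every
compound belongs to the FaSSIF modelling set (all 86 carry a Tr/Te label),
so FaSSIF is always present; the assignment of the remaining values was
solved by exhaustive enumeration against the printed per-medium minima,
maxima, medians and the dataset counts (86 FaSSIF, 48 HIF). Per row:

- Three printed values: buffer pH 6.5, FaSSIF, HIF in column order
  (45 compounds).
- One printed value: FaSSIF only (20 compounds): Azelnidipine, Bicalutamide, Bromazepam, Bromocriptine, Celecoxib, Efavirenz, Fluoxetine, Halofantrine, Isotretinoin, Nefazodone, Riluzole, Salsalate, Sertraline, Spironolactone, Tamsulosin, Telmisartan, Tolectin, Troglitazone, Voriconazole, Zafirlukast.
- Two printed values assigned FaSSIF + HIF (3 compounds): Cilostazole, Ibuprofen, Lansoprazole.
  Ibuprofen is forced: read as buffer+FaSSIF its -2.17 would exceed the
  printed buffer maximum of -2.19, and its -2.02 is required for the printed
  HIF maximum. Cilostazole and lansoprazole complete the printed medians
  (buffer -4.38 over n = 63; HIF -4.005, printing as -4.00) and the HIF
  count of 48.
- Two printed values assigned buffer + FaSSIF (18 compounds): Amitriptyline, Cisapride, Digoxin, Disopyramide, Haloperidol, Indoprofen, Ivermectin, Loperamide, Lorazepam, Nevirapine, Panadiplon, Phenazopyridine, Phenytoin, Pranlukast, Praziquantel, Rofecoxib, Terfenadine, Tolfenamic acid.

Under this curation 63/86 = 73% of compounds carry a buffer value; the
source text's "76%" is taken as approximate, since no assignment consistent
with the printed extreme rows and counts reaches 65.
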