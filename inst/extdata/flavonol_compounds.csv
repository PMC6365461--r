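compound,class
myricetin-3-O-glucoside,myricetin
quercetin-3-O-galactoside,quercetin
quercetin-3-O-glucuronide,quercetin
quercetin-3-O-glucoside,quercetin
kaempferol-3-O-glucoside,kaempferol
isorhamnetin-3-O-glucoside,isorhamnetin
laricitrin-3-O-glucoside,laricitrin
laricitin-3-O-glucoside,laricitrin
syringetin-3-O-glucoside,syringetin
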