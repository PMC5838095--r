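region,larvae_collected,p0_lines_established,lines_f1_larvae,lines_f1_adults,lines_f2_screened
Los Monegros,410,126,55,52,50
Bajo Cinca,493,147,63,61,60
Tafalla,387,101,33,32,26
Valdejalon,37,11,3,2,1
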