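key,descriptor,value,reference
CP_C12H20Cl6,log_kow,6.20,synthetic placeholder for a chlorinated-paraffin literature value
PCB151+PCB82,log_kow,6.45,synthetic placeholder for an experimentally derived coelution value
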