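pt
alanine aminotransferase increased
aspartate aminotransferase increased
transaminases increased
hepatic enzyme increased
hepatic enzyme abnormal
liver function test abnormal
liver function test increased
hepatic function abnormal
blood bilirubin increased
bilirubin conjugated increased
blood alkaline phosphatase increased
gamma-glutamyltransferase increased
hyperbilirubinaemia
hyperbilirubinemia
hepatotoxicity
liver injury
drug-induced liver injury
hepatocellular injury
cholestatic liver injury
mixed liver injury
liver disorder
hepatic failure
acute hepatic failure
hepatic failure fatal
hepatitis
hepatitis acute
hepatitis fulminant
hepatitis toxic
hepatitis cholestatic
autoimmune hepatitis
jaundice
jaundice cholestatic
ocular icterus
cholestasis
hepatic necrosis
hepatic steatosis
hepatic cirrhosis
hepatomegaly
hepatic encephalopathy
hepatorenal syndrome
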