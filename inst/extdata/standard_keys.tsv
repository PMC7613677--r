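name	value_type	units	private	doc
EchoTime	number	s	FALSE	Echo time of the acquisition
RepetitionTime	number	s	FALSE	Sequence repetition time
InversionTime	number	s	FALSE	Inversion recovery time
MixingTime	number	s	FALSE	Mixing time (e.g. STEAM TM)
ExcitationFlipAngle	number	degree	FALSE	Nominal excitation flip angle
TxOffset	number	ppm	FALSE	Transmitter offset relative to the reference shift
AcquisitionStartTime	string	ISO8601	TRUE	Date-time at which the acquisition started
SequenceName	string	NA	FALSE	Scanner sequence identifier
ProtocolName	string	NA	FALSE	Scanner protocol name
SequenceTriggered	bool	NA	FALSE	Whether the sequence was physiologically triggered
WaterSuppressed	bool	NA	FALSE	Whether water suppression was applied
WaterSuppressionType	string	NA	FALSE	Water suppression method (e.g. VAPOR, CHESS)
PulseSequenceFile	string	NA	FALSE	Pulse sequence source file
EditCondition	string-array	NA	FALSE	Labels of the spectral-editing conditions
EditPulse	object	NA	FALSE	Description of the editing pulse(s)
Manufacturer	string	NA	FALSE	Scanner manufacturer
ManufacturersModelName	string	NA	FALSE	Scanner model name
DeviceSerialNumber	string	NA	TRUE	Scanner serial number
SoftwareVersions	string	NA	FALSE	Scanner software version
InstitutionName	string	NA	FALSE	Institution at which the data were acquired
InstitutionAddress	string	NA	TRUE	Address of the institution
RxCoil	string	NA	FALSE	Receive coil name
TxCoil	string	NA	FALSE	Transmit coil name
PatientPosition	string	NA	FALSE	Subject position in the scanner (e.g. HFS)
PatientName	string	NA	TRUE	Subject name
PatientID	string	NA	TRUE	Subject identifier
PatientDoB	string	NA	TRUE	Subject date of birth
PatientSex	string	NA	TRUE	Subject sex
PatientWeight	number	kg	TRUE	Subject weight
ConversionMethod	string	NA	FALSE	Program used to convert the data to this format
ConversionTime	string	ISO8601	FALSE	Date-time of the format conversion
OriginalFile	string-array	NA	TRUE	Names of the source data files
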